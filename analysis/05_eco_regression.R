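#!/usr/bin/env Rscript
# Three-period ecological regression of fertility on deprivation for every
# age x nationality stratum: per-period relative risks at the 95th-vs-5th
# percentile contrast with 95% credible intervals and period-change flags,
# compared against the ground truth the city was simulated with.

library(fertimap)

counts <- read_counts("results/synthetic_city/counts.csv")
graph <- read_gal("results/synthetic_city/adjacency.gal")
ind <- read_indicators("results/synthetic_city/indicators.csv")
idx <- compute_index(ind)
truth <- jsonlite::read_json("results/synthetic_city/truth.json")

mc <- mcmc_control(n_chains = 2, n_retained = 2000, burn_in = 1500,
                   thin = 2, seed = 42)
rr <- run_stratified_analysis(counts, idx, graph, mc)
write.csv(rr, "results/relative_risks_long.csv", row.names = FALSE)

wide <- rr_wide(rr)
write.csv(wide, "results/relative_risks_wide.csv", row.names = FALSE)

cat("Relative risks, 95th vs 5th deprivation percentile",
    "(* change P1->P2, + change P2->P3):\n\n")
print(wide, row.names = FALSE)

# recovery against ground truth for the narrow age groups
span <- idx$q95 - idx$q5
cat("\nCoverage of the true RR by the 95% credible intervals:\n")
for (key in names(truth)) {
  tr <- truth[[key]]
  rr_true <- exp(unlist(tr$beta) * span)
  parts <- strsplit(key, ":")[[1]]
  sub <- rr[rr$age_group == parts[1] & rr$nationality == parts[2], ]
  hit <- sub$lo95 <= rr_true & rr_true <= sub$hi95
  cat(sprintf("  %-16s true RR %s -> covered: %s\n", key,
              paste(sprintf("%.2f", rr_true), collapse = "/"),
              paste(hit, collapse = " ")))
}
cat(sprintf("\nMax split R-hat across strata: %.3f\n", max(rr$max_rhat)))
cat("Wrote results/relative_risks_long.csv and results/relative_risks_wide.csv\n")
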