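#!/usr/bin/env Rscript
# Construct the deprivation index from the five simulated census
# indicators, check its dominant-component structure, and export the
# per-tract scores, septiles and a septile choropleth.

library(fertimap)

ind <- read_indicators("results/synthetic_city/indicators.csv")
idx <- compute_index(ind)

cat(sprintf("First principal component explains %.1f%% of indicator variance\n",
            100 * idx$variance_explained))
cat(sprintf("Index standardized: mean %.2e, sd %.6f\n",
            mean(idx$x), sd(idx$x)))
cat(sprintf("Percentile span: q5 = %.3f, q95 = %.3f (contrast %.3f)\n",
            idx$q5, idx$q95, idx$q95 - idx$q5))
cat("Septile sizes:", as.integer(table(idx$septile)), "\n")

write.csv(data.frame(tract_id = names(idx$x), x = idx$x,
                     septile = idx$septile, row.names = NULL),
          "results/deprivation_index.csv", row.names = FALSE)

# choropleth on the lattice's unit-square polygons
lat <- generate_lattice(12, 12)
write_choropleth(idx$x, lattice_polygons(lat$tracts), "septile",
                 "results/deprivation_septiles.geojson")
cat("Wrote results/deprivation_index.csv and results/deprivation_septiles.geojson\n")
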