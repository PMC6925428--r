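#!/usr/bin/env Rscript
# Crude fertility rates per 1000 women by age group, nationality and
# period, pooled over tracts: the wide reporting table.

library(fertimap)

counts <- read_counts("results/synthetic_city/counts.csv")
tab <- rates_table(counts)

cat("Crude fertility rates (births per 1000 women), pooled over tracts:\n\n")
print(format(tab, digits = 3), row.names = FALSE)

write.csv(tab, "results/crude_rates.csv", row.names = FALSE)
cat("\nWrote results/crude_rates.csv\n")
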