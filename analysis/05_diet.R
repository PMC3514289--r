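#!/usr/bin/env Rscript
# Stomach-content composition: per-individual prey proportions averaged
# within site (mean and SD per prey class).

library(lakestream)

dir.create("results", showWarnings = FALSE)
diet <- read.delim("results/data/diet_counts.tsv", check.names = FALSE)
ds <- diet_summary(diet, diet$site)
write.table(ds, "results/diet_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (s in unique(ds$site)) {
  top <- ds[ds$site == s, ]
  top <- top[order(-top$mean_prop), ][1, ]
  cat(sprintf("%s (n = %d): dominated by %s (mean proportion %.2f, SD %.2f)\n",
              s, top$n, top$prey_class, top$mean_prop, top$sd_prop))
}
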