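#!/usr/bin/env Rscript
# Stage 2 -- fairness of the allocation.
#
# Population-weighted Theil-T index for each resource indicator and year,
# decomposed into within-region and between-region inequality with
# contribution rates. The generator allocates per-capita resources by region
# multipliers plus unit-level noise, so both components are active.

library(healthalloc)

panel <- read_panel(file.path("results", "panel.csv"), require_regions = TRUE)
tab <- theil_table(panel)
write_report_table(tab, file.path("results", "theil.csv"), digits = 4)

cat(sprintf("theil table: %d indicator-years -> results/theil.csv\n", nrow(tab)))
worst <- tab[which.max(tab$total), ]
cat(sprintf("most unequal indicator-year: %s %d (T = %.4f)\n",
            worst$indicator, worst$year, worst$total))
cat(sprintf("mean contribution: between %.1f%%, within %.1f%%\n",
            mean(tab$between_contribution), mean(tab$within_contribution)))
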