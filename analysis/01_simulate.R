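#!/usr/bin/env Rscript
# Stage 1 -- build the study panel.
#
# The yearbook panel behind the published provincial results is not publicly
# deposited, so the workflow runs on a synthetic stand-in with the same
# shape: 31 provinces in three regions (11 eastern / 8 central / 12 western),
# six years, five resource inputs plus expenses, three service outputs,
# population weights and context covariates. Ground truth (frontier
# efficiency per unit-year) is written alongside so later stages can be
# checked against it.

library(healthalloc)

dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 20140101 %% 2^20)
sim <- generate_panel(cfg)

write_panel(sim$panel, file.path("results", "panel.csv"))
utils::write.csv(sim$truth$efficiency, file.path("results", "truth.csv"),
                 row.names = FALSE)

p <- sim$panel
cat(sprintf("panel: %d provinces x %d years (%d rows) -> results/panel.csv\n",
            length(unique(p$unit_id)), length(unique(p$year)), nrow(p)))
cat(sprintf("true efficiency: mean %.3f, range %.3f-%.3f -> results/truth.csv\n",
            mean(sim$truth$efficiency$efficiency),
            min(sim$truth$efficiency$efficiency),
            max(sim$truth$efficiency$efficiency)))
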