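#!/usr/bin/env Rscript
# Stage 3 -- static efficiency.
#
# Input-oriented CCR and BCC envelopment programs per province and year:
# comprehensive efficiency (TE), pure technical efficiency (PTE), scale
# efficiency (SE = TE/PTE) and returns-to-scale labels, plus slack-based
# projection targets (input redundancy, output insufficiency) for the
# provinces below the VRS frontier in the final year.

library(healthalloc)

panel <- read_panel(file.path("results", "panel.csv"), require_regions = TRUE)
cfg <- analysis_config()

scores <- dea_all_years(panel, cfg)
write_report_table(scores, file.path("results", "dea_by_year.csv"), digits = 3)

last <- max(panel$year)
static <- dea_year_table(panel, last, cfg)
write_report_table(static, file.path("results", "dea_static.csv"), digits = 3)
proj <- projection_table(panel, last, cfg)
write_report_table(proj, file.path("results", "projections.csv"), digits = 3)

for (yr in sort(unique(scores$year))) {
  s <- dea_summary(scores[scores$year == yr, ],
                   effective_threshold = cfg$effective_threshold)
  cat(sprintf("%d: mean TE %.3f, PTE %.3f, SE %.3f, %d/%d effective\n",
              yr, s$mean_te, s$mean_pte, s$mean_se, s$effective_count, s$n))
}
ineff <- unique(proj$unit_id)
cat(sprintf("%d provinces below the %d VRS frontier -> results/projections.csv\n",
            length(ineff), last))
red <- proj[proj$kind == "input_redundancy", ]
cat(sprintf("largest input redundancy rate: %s %s (%.1f%%)\n",
            red$unit_id[which.max(red$rate_percent)],
            red$indicator[which.max(red$rate_percent)],
            max(red$rate_percent)))
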