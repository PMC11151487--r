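#!/usr/bin/env Rscript

## Stage 9 -- disease-free evaluation of the signature on the augmentation
## cohort: z > 2 on any signature gene marks a sample altered; Kaplan-Meier
## curves and the log-rank test contrast the two groups.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("survival", cfg, run_dir)

km <- jsonlite::read_json(file.path(run_dir, "survival_summary.json"),
                          simplifyVector = TRUE)
for (i in seq_len(nrow(km$summary))) {
  cat(sprintf("  %s: n = %d, events = %d, median = %.2f months\n",
              km$summary$group[i], km$summary$n[i], km$summary$events[i],
              km$summary$median_months[i]))
}
cat(sprintf("Log-rank: chi-square = %.2f, p = %.3g\n",
            km$logrank_chisq, km$logrank_p))
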