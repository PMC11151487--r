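## Shared configuration for the analysis drivers. Every driver sources this
## file, then runs one pipeline stage against the shared run directory
## `results/run/` so intermediate tables accumulate there.
##
## The cohort design mirrors the emulated study (7 paired patients on a
## 760-gene panel; a 373-sample primary-only augmentation cohort, 13 of
## which carry excluded histologies). Model training sizes are reduced from
## the package defaults (fewer enrichment terms, 50 epochs) so the whole
## driver sequence completes in a few minutes on a laptop; the stage logic
## is identical at any scale.

library(pathsig)

run_dir <- file.path("results", "run")

analysis_config <- function(seed = 20240605) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$n_terms <- 20
  cfg$n_signal_terms <- 6
  cfg$signal_genes_per_term <- 20
  cfg$de_frac <- 0.1
  cfg$effect_log2fc <- 1.5
  cfg$n_augmentation <- 373
  cfg$epochs <- 50
  validate_config(cfg)
  cfg
}
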