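#!/usr/bin/env Rscript

## Stage 2 -- nCounter-style normalization: positive-control scaling,
## negative-control background threshold, geNorm reference selection and
## housekeeping normalization.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("normalize", cfg, run_dir)

info <- jsonlite::read_json(file.path(run_dir, "normalization.json"),
                            simplifyVector = TRUE)
cat(sprintf("Background threshold (mean + 2 SD of negatives): %.2f\n",
            info$threshold))
cat(sprintf("%d genes retained above background; geNorm references: %s\n",
            length(info$retained_genes),
            paste(info$genorm_references, collapse = ", ")))
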