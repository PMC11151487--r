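#!/usr/bin/env Rscript

## Stage 1 -- generate the synthetic study: paired primary/recurrent counts
## with control probes, the primary-only augmentation cohort with histology
## labels, pathway and GO collections around the planted DE genes, an
## immune signature with mixtures, and the serialized ground truth.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("simulate", cfg, run_dir)

truth <- jsonlite::read_json(file.path(run_dir, "truth.json"))
meta <- read_metadata(file.path(run_dir, "metadata.tsv"))
cat(sprintf("Simulated %d paired patients on a %d-gene panel (%d planted DE genes)\n",
            length(unique(meta$patient_id)), cfg$n_genes,
            length(truth$de_genes)))
cat(sprintf("Augmentation cohort: %d samples written with histology labels\n",
            cfg$n_augmentation))
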