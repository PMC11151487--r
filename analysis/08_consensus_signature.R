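#!/usr/bin/env Rscript

## Stage 8 -- Shapley attribution on the high-performing bootstraps, the
## consensus rule (importance >= 0.01 in at least half of the models with
## test accuracy strictly above 0.80), gene discriminant scores across
## terms and the top-20 signature.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("consensus", cfg, run_dir)

sel <- read.delim(file.path(run_dir, "consensus_selections.tsv"))
sig <- readLines(file.path(run_dir, "signature.txt"))
truth <- jsonlite::read_json(file.path(run_dir, "truth.json"))
cat(sprintf("Consensus selections: %d (gene, term) pairs over %d terms\n",
            nrow(sel), length(unique(sel$term_id))))
cat(sprintf("Top-%d signature: %s\n", length(sig), paste(sig, collapse = ", ")))
cat(sprintf("Signature genes among planted DE genes: %d of %d\n",
            sum(sig %in% unlist(truth$de_genes)), length(sig)))
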