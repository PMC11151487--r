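#!/usr/bin/env Rscript

## Stage 7 -- the pathway-centric pairwise classifiers: merge the study and
## augmentation cohorts on shared genes, standardize each sample within
## each curated term, build primary-primary / primary-recurrent pairs with
## a sample-level train/test split, and train the 16-filter convolutional
## model for 10 bootstrap re-partitions per term.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("train", cfg, run_dir)

metrics <- read.delim(file.path(run_dir, "model_metrics.tsv"))
summ <- read.delim(file.path(run_dir, "model_metrics_summary.tsv"))
cat(sprintf("Trained %d bootstrap models over %d terms\n",
            nrow(metrics), length(unique(metrics$term_id))))
for (i in seq_len(nrow(summ))) {
  cat(sprintf("  median %s: %.3f\n", summ$metric[i], summ$median[i]))
}
high <- sum(metrics$accuracy > cfg$acc_cut)
cat(sprintf("High-performing models (accuracy > %.2f): %d of %d\n",
            cfg$acc_cut, high, nrow(metrics)))
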