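#!/usr/bin/env Rscript

## Stage 3 -- paired differential expression (recurrent vs primary):
## per-patient log2 differences, paired t-test, BH q-values, DEG filter at
## q <= 0.05 and |fold change| >= 1.5.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("de", cfg, run_dir)

tab <- read.delim(file.path(run_dir, "deg_table.tsv"))
truth <- jsonlite::read_json(file.path(run_dir, "truth.json"))
degs <- tab$gene[tab$direction != "none"]
cat(sprintf("DEGs at q <= %.2f and |FC| >= %.1f: %d (%d up, %d down)\n",
            cfg$q_cut, cfg$fc_cut, length(degs),
            sum(tab$direction == "up"), sum(tab$direction == "down")))
cat(sprintf("Planted effects recovered: %.0f%%\n",
            100 * mean(unlist(truth$de_genes) %in% degs)))
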