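#!/usr/bin/env Rscript

## Stage 4 -- over-representation of the DEG list against the pathway and
## GO collections: report tier (adjusted p < 0.001, top 10 per category),
## curation tier for the classifiers (adjusted p < 0.05 with >= 5 DE genes
## per pathway, >= 10 per GO term), and the bridge-gene analysis over the
## top 5 terms per category (>= 5 links per gene).

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("enrich", cfg, run_dir)

rep_tab <- read.delim(file.path(run_dir, "enrichment_report.tsv"))
curated <- readLines(file.path(run_dir, "curated_terms.gmt"))
bridge <- read.delim(file.path(run_dir, "bridge_genes.tsv"))
cat(sprintf("Report-tier terms (adj p < %.3g): %d\n",
            cfg$enrich_report_cut, nrow(rep_tab)))
cat(sprintf("Curated for the classifier stage: %d terms\n", length(curated)))
cat(sprintf("Bridge genes (>= %d links): %s\n", cfg$min_links,
            paste(bridge$gene, collapse = ", ")))
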