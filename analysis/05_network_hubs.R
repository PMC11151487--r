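#!/usr/bin/env Rscript

## Stage 5 -- hub ranking of the DEG interaction network by Maximal Clique
## Centrality (sum of (|C|-1)! over maximal cliques containing the node).

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("hubs", cfg, run_dir)

hubs <- read.delim(file.path(run_dir, "hub_genes.tsv"))
edges <- read.delim(file.path(run_dir, "ppi_edges.tsv"))
cat(sprintf("Interaction network: %d edges among DEGs\n", nrow(edges)))
cat(sprintf("Top %d hubs by MCC: %s\n", nrow(hubs),
            paste(hubs$gene, collapse = ", ")))
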