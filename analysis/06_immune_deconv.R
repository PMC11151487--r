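#!/usr/bin/env Rscript

## Stage 6 -- immune-cell composition per sample by non-negative least
## squares against the 22-type signature, and paired signed-rank comparison
## of fractions between primary and recurrent tumors.

source(file.path("analysis", "00_config.R"))
cfg <- analysis_config()

run_stage("deconv", cfg, run_dir)

cmp <- read.delim(file.path(run_dir, "immune_comparison.tsv"))
sig_types <- cmp[!is.na(cmp$p_value) & cmp$p_value <= 0.05, ]
cat(sprintf("Cell types compared: %d; significant at p <= 0.05: %d\n",
            nrow(cmp), nrow(sig_types)))
if (nrow(sig_types)) {
  for (i in seq_len(nrow(sig_types))) {
    cat(sprintf("  %s: median diff %+.3f, p = %.4f\n",
                sig_types$cell_type[i], sig_types$median_diff[i],
                sig_types$p_value[i]))
  }
}
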