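# pathsig

Pathway-centric deep-learning gene signatures for tumor recurrence, as an
R analysis pipeline.

## The problem

Recurrence after curative treatment of hepatocellular carcinoma is
aggressive and transcriptomically under-characterized: matched
primary/recurrent tumor pairs are rare, so a typical cohort is a handful
of patients profiled on a targeted digital-count panel (~760 genes with
positive/negative/housekeeping control probes). `pathsig` implements a
complete analysis for that setting, aimed at computational biologists who
want every stage scripted, seeded and testable:

1. **Normalization** — positive-control scaling, background thresholding
   from negative controls (mean + 2 SD), geNorm reference-gene selection
   (stability statistic *M* = mean SD of pairwise log-ratios) and
   housekeeping normalization.
2. **Paired differential expression** — per-patient log2 differences,
   paired t-test, Benjamini–Hochberg q-values; DEGs at q ≤ 0.05 and
   |FC| ≥ 1.5.
3. **Enrichment** — hypergeometric over-representation against pathway
   and GO collections with per-category BH adjustment; a report tier
   (adj. p < 0.001) and a curation tier feeding the classifiers
   (adj. p < 0.05 with ≥ 5 DE genes per pathway, ≥ 10 per GO term);
   bridge genes with ≥ 5 links over the top 5 terms per category.
4. **Network hubs** — Maximal Clique Centrality,
   MCC(v) = Σ<sub>C∋v</sub> (|C|−1)! over exact maximal cliques.
5. **Immune deconvolution** — non-negative least squares against a
   22-cell-type signature, fractions summing to one; paired Wilcoxon
   signed-rank comparisons with exact small-sample nulls.
6. **The pairwise classifier** — the core method. Instances are sample
   *pairs* (primary–primary vs primary–recurrent) over one curated term's
   genes, each sample standardized within the term; a small convolutional
   network (16 filters with a 1×2 kernel across the pair, dense 32/16,
   softmax, Adagrad) is trained over 10 random train/test re-partitions
   per term, with samples split before pairing so nothing leaks.
7. **Shapley consensus signature** — Monte-Carlo Shapley attribution of
   the PR-class output per gene; a gene passes a term when its importance
   reaches 0.01 in at least half of the bootstraps with accuracy strictly
   above 0.80; the gene discriminant score counts selecting terms and the
   top 20 form the signature.
8. **Survival** — samples with any signature gene at z > 2 form the
   altered group; Kaplan–Meier medians and the log-rank test compare the
   groups.

Synthetic-data generators with serialized ground truth (negative-binomial
paired cohorts with control probes, a 373-sample augmentation cohort with
histology exclusions, gene sets with planted signal, immune mixtures,
exponential survival) make every stage runnable and checkable offline.

## Worked example

The numbered drivers under `analysis/` run the nine stages against a
shared run directory, `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_diffexpr.R
# ... through analysis/09_survival.R
```

Output of a full sequence (seed 20240605, the committed defaults;
abridged to the headline lines each driver prints):

```
Simulated 7 paired patients on a 760-gene panel (76 planted DE genes)
Background threshold (mean + 2 SD of negatives): 4.51
DEGs at q <= 0.05 and |FC| >= 1.5: 56 (48 up, 8 down)
Planted effects recovered: 68%
Report-tier terms (adj p < 0.001): 5
Curated for the classifier stage: 6 terms
Bridge genes (>= 5 links): G0514, G0077, G0384, G0635
Top 10 hubs by MCC: G0007, G0077, G0015, G0115, G0097, G0091, G0037, G0088, G0112, G0069
Cell types compared: 22; significant at p <= 0.05: 3
  cell_type_01: median diff +0.103, p = 0.0156
Trained 60 bootstrap models over 6 terms
  median accuracy: 0.983
High-performing models (accuracy > 0.80): 60 of 60
Top-10 signature: G0112, G0200, G0489, G0698, G0635, G0077, G0384, G0007, G0219, G0123
Signature genes among planted DE genes: 10 of 10
  altered: n = 22, events = 17, median = 13.17 months
  unaltered: n = 338, events = 259, median = 34.53 months
Log-rank: chi-square = 17.38, p = 3.06e-05
```

Reading it: the paired design recovers 68% of the planted 1.5-fold
effects at panel scale (seven pairs is a small design; larger planted
effects are recovered almost completely — the test suite measures this);
the curation tier finds exactly the six terms built around the planted
genes; the deconvolution recovers the planted composition shift
(cell type 1 up in recurrent tumors); the consensus is conservative at
this scale — it selects 10 genes, every one a planted DE gene — and the
signature's altered group shows the expected shorter disease-free median.

Equivalently, one call runs everything: `run_stage("all", config, outdir)`.

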