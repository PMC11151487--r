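## Ground-truth generators for every input the pipeline consumes: a paired
## negative-binomial count cohort on a targeted panel with control probes, a
## primary-only augmentation cohort with histology labels, gene-set
## collections with planted discriminative genes, an immune signature matrix
## with known mixing fractions, and exponential survival times with a
## group-dependent hazard. Every generator is a pure function of its
## parameters and seed, and the truth is returned alongside the data.

#' Simulate a paired primary/recurrent count cohort with control probes
#'
#' Negative-binomial counts for `n_patients` patients, two samples each
#' (primary and recurrent), on an `n_genes` panel. Patient-level random
#' effects and per-sample technical factors induce realistic correlation;
#' planted DE genes are shifted in the recurrent samples by
#' `effect_log2fc` (a small fraction shifted down). Control probes follow
#' the panel layout: 6 positive controls on a geometric ladder tracking the
#' technical factor, 8 negative controls near zero, and housekeeping genes
#' whose means track library size.
#'
#' @param n_patients number of paired patients
#' @param n_genes endogenous panel size
#' @param de_frac fraction of genes planted as differentially expressed
#' @param effect_log2fc planted log2 fold change (recurrent vs primary)
#' @param dispersion central NB dispersion (gene dispersions are log-normal
#'   around this value)
#' @param n_housekeeping housekeeping candidate genes appended to the panel
#' @param down_frac fraction of planted DE genes shifted down
#' @param seed RNG seed
#' @return list: `counts` (expression matrix incl. housekeeping rows),
#'   `controls` (a [control_set()]), `meta` (sample metadata), `truth`
#'   (planted DE genes/effects and all generator parameters)
#' @export
simulate_paired_cohort <- function(n_patients = 7, n_genes = 760,
                                   de_frac = 0.1, effect_log2fc = 1.5,
                                   dispersion = 0.1, n_housekeeping = 12,
                                   down_frac = 0.05, seed = 1) {
  stopifnot(de_frac >= 0, de_frac <= 1, n_patients >= 2, n_genes >= 10,
            dispersion > 0, down_frac >= 0, down_frac <= 1)
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    hk <- sprintf("HK%02d", seq_len(n_housekeeping))
    samples <- as.vector(rbind(sprintf("P%02d_primary", seq_len(n_patients)),
                               sprintf("P%02d_recurrent", seq_len(n_patients))))
    tissue <- rep(c("primary", "recurrent"), n_patients)
    patient <- rep(sprintf("P%02d", seq_len(n_patients)), each = 2)

    base_mu <- stats::rlnorm(n_genes, meanlog = log(150), sdlog = 1.1)
    disp <- stats::rlnorm(n_genes, meanlog = log(dispersion), sdlog = 0.4)
    pat_eff <- stats::rlnorm(n_patients, sdlog = 0.15)[rep(seq_len(n_patients), each = 2)]
    tech <- stats::rlnorm(2 * n_patients, sdlog = 0.25)

    n_de <- round(de_frac * n_genes)
    de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
    sign_vec <- stats::setNames(rep(1, n_de), de_genes)
    if (n_de > 0) {
      n_down <- round(down_frac * n_de)
      if (n_down > 0) sign_vec[sample(de_genes, n_down)] <- -1
    }

    mu <- outer(base_mu, pat_eff * tech)
    rownames(mu) <- genes
    if (n_de > 0) {
      rec <- tissue == "recurrent"
      mu[de_genes, rec] <- mu[de_genes, rec] * 2^(effect_log2fc * sign_vec)
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / disp),
                     nrow = n_genes, dimnames = list(genes, samples))

    lib <- colSums(counts) / mean(colSums(counts))
    hk_mu <- outer(stats::rlnorm(n_housekeeping, meanlog = log(600), sdlog = 0.4), lib)
    hk_counts <- matrix(stats::rnbinom(length(hk_mu), mu = hk_mu, size = 60),
                        nrow = n_housekeeping, dimnames = list(hk, samples))

    pos_ladder <- c(16384, 4096, 1024, 256, 64, 16)
    pos <- vapply(seq_along(samples), function(s) {
      stats::rpois(6, lambda = pos_ladder * tech[s])
    }, numeric(6))
    dimnames(pos) <- list(sprintf("POS_%s", LETTERS[1:6]), samples)
    neg <- matrix(stats::rpois(8 * length(samples), lambda = 2), nrow = 8,
                  dimnames = list(sprintf("NEG_%s", LETTERS[1:8]), samples))

    meta <- data.frame(sample_id = samples, patient_id = patient,
                       tissue_class = tissue, cohort = "study",
                       histology_label = "hcc", stringsAsFactors = FALSE)
    list(counts = expression_matrix(rbind(counts, hk_counts), scale_tag = "raw_counts"),
         controls = control_set(pos, neg, hk),
         meta = validate_metadata(meta),
         truth = list(de_genes = de_genes,
                      effects_log2 = effect_log2fc * sign_vec,
                      params = list(n_patients = n_patients, n_genes = n_genes,
                                    de_frac = de_frac,
                                    effect_log2fc = effect_log2fc,
                                    dispersion = dispersion,
                                    down_frac = down_frac, seed = seed)))
  })
}

#' Simulate the primary-only augmentation cohort
#'
#' Negative-binomial counts for `n_total` primary samples on the same gene
#' panel, with histology labels arranged so the exclusion filter retains
#' `n_total` minus the labelled exclusions. Per-gene means are deliberately
#' shifted relative to `reference_mu` (a global scale factor plus per-gene
#' log-normal jitter) to emulate cross-platform marginals.
#'
#' @param gene_ids panel gene ids (use the paired cohort's endogenous genes)
#' @param n_total cohort size before filtering
#' @param exclusions named integer vector: histology label -> sample count
#' @param reference_mu optional per-gene reference means to shift from
#' @param scale_shift global mean multiplier versus the reference
#' @param seed RNG seed
#' @return list: `counts`, `meta`, `truth`
#' @export
simulate_augmentation_cohort <- function(gene_ids, n_total = 373,
                                         exclusions = c(combined_hcc_chol = 8,
                                                        fibrolamellar = 3,
                                                        recurrent_tissue = 2),
                                         reference_mu = NULL,
                                         scale_shift = 2.5, seed = 1) {
  if (n_total <= sum(exclusions)) stop("n_total must exceed total exclusions")
  with_seed(seed, {
    n_genes <- length(gene_ids)
    samples <- sprintf("TCGA%04d", seq_len(n_total))
    if (is.null(reference_mu)) {
      reference_mu <- stats::rlnorm(n_genes, meanlog = log(150), sdlog = 1.1)
    }
    mu_gene <- reference_mu * scale_shift * stats::rlnorm(n_genes, sdlog = 0.4)
    lib <- stats::rlnorm(n_total, sdlog = 0.2)
    mu <- outer(mu_gene, lib)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / 0.4),
                     nrow = n_genes, dimnames = list(gene_ids, samples))
    labels <- rep("hcc", n_total)
    if (length(exclusions)) {
      idx <- sample(n_total, sum(exclusions))
      labels[idx] <- rep(names(exclusions), times = exclusions)
    }
    meta <- data.frame(sample_id = samples, patient_id = samples,
                       tissue_class = "primary", cohort = "augmentation",
                       histology_label = labels, stringsAsFactors = FALSE)
    list(counts = expression_matrix(counts, scale_tag = "raw_counts"),
         meta = validate_metadata(meta),
         truth = list(exclusions = exclusions, scale_shift = scale_shift,
                      seed = seed))
  })
}

#' Simulate a gene-set collection with designated signal terms
#'
#' Random term memberships over the gene universe (sizes uniform in
#' `size_range`), split between pathway and GO biological-process
#' categories. Signal terms are forced to contain their signal genes.
#'
#' @param universe gene ids to draw from
#' @param n_terms total terms (half pathway, half go_bp)
#' @param size_range term size range
#' @param signal_terms named list: term id (e.g. "TERM03") -> signal gene ids
#' @param seed RNG seed
#' @return gene-set collection data.frame (as from [read_gmt()])
#' @export
simulate_gene_sets <- function(universe, n_terms = 40, size_range = c(10, 60),
                               signal_terms = list(), seed = 1) {
  with_seed(seed, {
    ids <- sprintf("TERM%02d", seq_len(n_terms))
    category <- rep(c("pathway", "go_bp"), length.out = n_terms)
    genes <- lapply(seq_len(n_terms), function(i) {
      size <- sample(size_range[1]:size_range[2], 1)
      members <- sample(universe, size)
      extra <- signal_terms[[ids[i]]]
      if (!is.null(extra)) members <- unique(c(extra, members))
      members
    })
    data.frame(term_id = ids,
               term_name = sprintf("synthetic %s %02d", category, seq_len(n_terms)),
               category = category, genes = I(genes), stringsAsFactors = FALSE)
  })
}

#' Plant a class signal on selected genes
#'
#' Shifts the recurrent samples by `shift_sd` per-gene standard deviations
#' (SD measured across all samples) on the signal genes, leaving every other
#' gene untouched. Works on any additive scale (normalized or log).
#'
#' @param mat expression matrix
#' @param signal_genes genes to shift
#' @param recurrent_ids columns receiving the shift
#' @param shift_sd shift size in per-gene SD units
#' @return list: `matrix` (shifted), `truth` (signal genes and shift)
#' @export
plant_term_signal <- function(mat, signal_genes, recurrent_ids, shift_sd) {
  miss <- setdiff(signal_genes, rownames(mat))
  if (length(miss)) stop("signal gene(s) absent: ", paste(miss, collapse = ", "))
  out <- mat
  if (shift_sd != 0 && length(signal_genes)) {
    sds <- apply(mat[signal_genes, , drop = FALSE], 1, stats::sd)
    out[signal_genes, recurrent_ids] <-
      out[signal_genes, recurrent_ids] + shift_sd * sds
  }
  list(matrix = out, truth = list(signal_genes = signal_genes,
                                  shift_sd = shift_sd))
}

#' Simulate an immune signature matrix
#'
#' Marker-block reference: each cell type gets `markers_per_type` dedicated
#' high-expression marker genes over a low shared baseline, giving full
#' column rank.
#'
#' @param n_cell_types number of cell types (22 matches the standard panel)
#' @param markers_per_type dedicated markers per type
#' @param marker_level,baseline_level expression levels
#' @param seed RNG seed
#' @return genes x cell-types non-negative matrix
#' @export
simulate_signature_matrix <- function(n_cell_types = 22, markers_per_type = 10,
                                      marker_level = 100, baseline_level = 2,
                                      seed = 1) {
  with_seed(seed, {
    n_genes <- n_cell_types * markers_per_type
    genes <- sprintf("IMM%03d", seq_len(n_genes))
    types <- sprintf("cell_type_%02d", seq_len(n_cell_types))
    sig <- matrix(stats::runif(n_genes * n_cell_types, 0, baseline_level),
                  n_genes, n_cell_types, dimnames = list(genes, types))
    for (ct in seq_len(n_cell_types)) {
      rows <- ((ct - 1) * markers_per_type + 1):(ct * markers_per_type)
      sig[rows, ct] <- sig[rows, ct] +
        stats::runif(markers_per_type, 0.5, 1.5) * marker_level
    }
    sig
  })
}

#' Simulate bulk mixtures of a signature matrix
#'
#' @param sig signature matrix (genes x cell types)
#' @param fractions samples x cell-types matrix of true fractions (rows sum
#'   to 1); or an integer to draw that many Dirichlet-like fraction vectors
#' @param noise_sd multiplicative Gaussian noise SD (0 = noiseless)
#' @param seed RNG seed
#' @return list: `expr` (genes x samples), `fractions` (truth)
#' @export
simulate_mixtures <- function(sig, fractions = 5, noise_sd = 0, seed = 1) {
  with_seed(seed, {
    if (is.numeric(fractions) && length(fractions) == 1) {
      n <- fractions
      raw <- matrix(stats::rgamma(n * ncol(sig), shape = 0.8), n, ncol(sig))
      fractions <- raw / rowSums(raw)
      colnames(fractions) <- colnames(sig)
    }
    expr <- sig %*% t(fractions)
    if (noise_sd > 0) {
      expr <- expr * matrix(stats::rnorm(length(expr), 1, noise_sd),
                            nrow(expr), ncol(expr))
      expr[expr < 0] <- 0
    }
    colnames(expr) <- sprintf("MIX%03d", seq_len(ncol(expr)))
    rownames(fractions) <- colnames(expr)
    list(expr = expr, fractions = fractions)
  })
}

#' Simulate survival times with a group-dependent hazard
#'
#' Exponential event times: the unaltered group has median
#' `median_unaltered_months` (rate log(2)/median); the altered group's rate
#' is multiplied by `hr`. Independent censoring marks a `censor_frac`
#' fraction of subjects censored at a uniform fraction of their event time.
#' The defaults encode the emulated disease-free contrast: an unaltered
#' median of 29.66 months and a hazard ratio putting the altered median at
#' 15.70 months (exponential medians scale as 1/hr).
#'
#' @param groups named character vector sample -> "altered"/"unaltered"
#' @param hr hazard ratio of altered vs unaltered (> 0)
#' @param median_unaltered_months median survival of the unaltered group
#' @param censor_frac expected fraction censored
#' @param seed RNG seed
#' @return data.frame sample, time, event, group
#' @export
simulate_survival <- function(groups, hr = 29.66 / 15.70,
                              median_unaltered_months = 29.66,
                              censor_frac = 0.2, seed = 1) {
  stopifnot(hr > 0, censor_frac >= 0, censor_frac <= 1)
  with_seed(seed, {
    rate <- log(2) / median_unaltered_months
    rates <- ifelse(groups == "altered", rate * hr, rate)
    t_event <- stats::rexp(length(groups), rate = rates)
    censored <- stats::runif(length(groups)) < censor_frac
    time <- ifelse(censored, t_event * stats::runif(length(groups)), t_event)
    data.frame(sample = names(groups), time = time,
               event = as.integer(!censored), group = unname(groups),
               stringsAsFactors = FALSE)
  })
}
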