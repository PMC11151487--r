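## Count normalization for nCounter-style panels: positive-control scaling,
## negative-control background thresholding, geNorm reference-gene selection
## and housekeeping normalization. Order of application in the wrapper
## mirrors the platform's documented sequence: positive factor, background
## flagging, housekeeping normalization.

#' Assemble a control-probe set
#'
#' @param positive_controls matrix, positive control probes x samples (6 on
#'   a standard panel)
#' @param negative_controls matrix, negative control probes x samples (8 on
#'   a standard panel)
#' @param housekeeping_genes candidate reference gene ids (>= 2 for geNorm)
#' @return list of class `control_set`
#' @export
control_set <- function(positive_controls, negative_controls, housekeeping_genes) {
  positive_controls <- as.matrix(positive_controls)
  negative_controls <- as.matrix(negative_controls)
  if (any(positive_controls < 0) || any(negative_controls < 0)) {
    stop("control counts must be non-negative")
  }
  if (length(negative_controls) < 2) stop("need >= 2 negative-control observations")
  if (length(housekeeping_genes) < 2) stop("need >= 2 housekeeping candidates")
  structure(list(positive_controls = positive_controls,
                 negative_controls = negative_controls,
                 housekeeping_genes = as.character(housekeeping_genes)),
            class = "control_set")
}

#' Background threshold from negative controls
#'
#' Pools all negative-control observations (controls x samples) and returns
#' mean + 2 standard deviations (sample SD, n - 1). Genes whose count stays
#' below this threshold in every sample are treated as background; use
#' [background_filter()] to apply the exclusion.
#'
#' @param controls a `control_set` or a numeric matrix/vector of negative counts
#' @return scalar threshold
#' @export
background_threshold <- function(controls) {
  neg <- if (inherits(controls, "control_set")) controls$negative_controls else controls
  neg <- as.numeric(neg)
  if (length(neg) < 2) stop("need >= 2 negative-control observations")
  mean(neg) + 2 * stats::sd(neg)
}

#' @rdname background_threshold
#' @param mat expression matrix (raw or positive-scaled counts)
#' @param threshold background threshold
#' @return character vector of retained gene ids (a gene is excluded only if
#'   below threshold in all samples)
#' @export
background_filter <- function(mat, threshold) {
  keep <- apply(mat, 1, function(x) any(x >= threshold))
  dropped <- sum(!keep)
  if (dropped > 0) {
    ps_log(sprintf("background_filter: %d gene(s) below threshold %.4g in every sample",
                   dropped, threshold), stage = "nanostring_norm")
  }
  rownames(mat)[keep]
}

#' Positive-control scale factors
#'
#' factor_s = (arithmetic mean over samples of the geometric mean of the
#' positive controls) / (geometric mean of positives in sample s). After
#' multiplying each sample by its factor the positive-control geometric
#' means are equal across samples.
#'
#' @param controls a `control_set` or positive-control matrix (controls x samples)
#' @return named numeric vector of per-sample factors
#' @export
positive_factor <- function(controls) {
  pos <- if (inherits(controls, "control_set")) controls$positive_controls else controls
  pos <- as.matrix(pos)
  if (any(pos <= 0)) stop("positive-control counts must be > 0 (log-undefined otherwise)")
  gm <- apply(pos, 2, geomean)
  mean(gm) / gm
}

#' geNorm stability statistic M
#'
#' For candidate j, M_j is the mean over the other candidates k of the
#' sample-wise standard deviation (n - 1) of log2(x_j) - log2(x_k). Stable
#' reference genes have small M. Input must already be on the log2 scale.
#'
#' @param log2_expr candidates x samples matrix of log2 expression
#' @return list: `stability_m` (named vector), `ranked_genes` (most stable
#'   first, ties by gene id), `selected_references` (all candidates)
#' @export
genorm_stability <- function(log2_expr) {
  log2_expr <- as.matrix(log2_expr)
  if (nrow(log2_expr) < 2) stop("need >= 2 candidates")
  if (ncol(log2_expr) < 2) stop("need >= 2 samples")
  if (!all(is.finite(log2_expr))) stop("non-finite log2 value among candidates")
  n <- nrow(log2_expr)
  m <- vapply(seq_len(n), function(j) {
    sds <- vapply(setdiff(seq_len(n), j), function(k) {
      stats::sd(log2_expr[j, ] - log2_expr[k, ])
    }, 0)
    mean(sds)
  }, 0)
  names(m) <- rownames(log2_expr)
  ord <- order(m, names(m))
  list(stability_m = m,
       ranked_genes = names(m)[ord],
       selected_references = rownames(log2_expr))
}

#' geNorm iterative reference selection
#'
#' Repeatedly removes the least stable candidate (highest M, ties broken by
#' removing the lexicographically last gene id) and recomputes M until
#' `target_count` remain.
#'
#' @param log2_expr candidates x samples log2 matrix
#' @param target_count number of references to keep (>= 2)
#' @return list: `stability_m` (final M of survivors plus M-at-removal of
#'   dropped genes), `ranked_genes` (survivors by final M, then removed genes
#'   in reverse removal order), `selected_references`
#' @export
genorm_select <- function(log2_expr, target_count) {
  log2_expr <- as.matrix(log2_expr)
  if (target_count < 2) stop("target_count must be >= 2")
  if (target_count > nrow(log2_expr)) {
    stop(sprintf("target_count (%d) exceeds candidate count (%d)",
                 target_count, nrow(log2_expr)))
  }
  removed <- character(0)
  m_at_removal <- numeric(0)
  cur <- log2_expr
  while (nrow(cur) > target_count) {
    st <- genorm_stability(cur)
    m <- st$stability_m
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]   # tie-break: drop last gene id
    removed <- c(removed, worst)
    m_at_removal <- c(m_at_removal, m[[worst]])
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  final <- genorm_stability(cur)
  stab <- c(final$stability_m, stats::setNames(m_at_removal, removed))
  list(stability_m = stab,
       ranked_genes = c(final$ranked_genes, rev(removed)),
       selected_references = final$ranked_genes)
}

#' Housekeeping normalization
#'
#' Scales each sample by (mean across samples of the reference-gene
#' geometric mean) / (reference geometric mean of the sample), so reference
#' geometric means are equal across samples afterwards.
#'
#' @param mat expression matrix on the linear scale
#' @param references reference gene ids present in `mat` with positive counts
#' @param offset count offset added inside the geometric-mean computation
#'   only (for zero-tolerant use on raw counts; logged when non-zero). With
#'   `offset = 0` (default) the post-normalization reference geometric means
#'   are exactly equal across samples.
#' @return normalized expression matrix (`scale_tag` = "normalized")
#' @export
housekeeping_normalize <- function(mat, references, offset = 0) {
  miss <- setdiff(references, rownames(mat))
  if (length(miss)) stop("reference gene(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  ref <- mat[references, , drop = FALSE] + offset
  if (any(ref <= 0)) stop("reference gene with non-positive count; offset counts first")
  if (offset != 0) {
    ps_log(sprintf("housekeeping_normalize: +%g offset inside geomeans", offset),
           stage = "nanostring_norm")
  }
  gm <- apply(ref, 2, geomean)
  factors <- mean(gm) / gm
  out <- sweep(mat, 2, factors, `*`)
  expression_matrix(out, scale_tag = "normalized")
}

#' Full nCounter-style normalization
#'
#' Positive-control scaling, then background flagging from the negative
#' controls, then geNorm selection of references from the housekeeping
#' candidates (on log2(count + offset)) and housekeeping normalization.
#' The +1 count offset used before log transforms is logged.
#'
#' @param mat raw count matrix (endogenous + housekeeping genes in rows)
#' @param controls a `control_set`
#' @param n_references number of geNorm references to keep
#' @param offset count offset applied before log2 in the geNorm step
#' @return list: `normalized` matrix (background-flagged genes removed,
#'   housekeeping rows retained), `threshold`, `retained_genes`,
#'   `positive_factors`, `genorm` result
#' @export
normalize_nanostring <- function(mat, controls, n_references = 5, offset = 1) {
  stopifnot(inherits(controls, "control_set"))
  pf <- positive_factor(controls)
  if (!all(colnames(mat) %in% names(pf)) &&
      length(pf) != ncol(mat)) {
    stop("positive controls do not cover all samples")
  }
  pf <- if (!is.null(names(pf)) && all(colnames(mat) %in% names(pf)))
    pf[colnames(mat)] else pf
  scaled <- sweep(mat, 2, pf, `*`)
  thr <- background_threshold(controls)
  hk <- intersect(controls$housekeeping_genes, rownames(scaled))
  if (length(hk) < 2) stop("fewer than 2 housekeeping candidates present in matrix")
  keep <- union(background_filter(scaled, thr), hk)
  keep <- rownames(scaled)[rownames(scaled) %in% keep]   # preserve order
  scaled <- scaled[keep, , drop = FALSE]
  ps_log(sprintf("normalize_nanostring: +%g count offset before log2 in geNorm", offset),
         stage = "nanostring_norm")
  gn <- genorm_select(log2(scaled[hk, , drop = FALSE] + offset),
                      target_count = min(n_references, length(hk)))
  normalized <- housekeeping_normalize(scaled, gn$selected_references,
                                       offset = offset)
  list(normalized = normalized, threshold = thr, retained_genes = keep,
       positive_factors = pf, genorm = gn)
}
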