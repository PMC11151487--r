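## Immune-cell composition from bulk expression: non-negative least squares
## against a cell-type signature matrix (22 immune cell types on the
## standard reference), fractions renormalized to sum to one, and paired
## Wilcoxon signed-rank comparisons of fractions between primary and
## recurrent tumors.

#' Deconvolve one or more samples against a signature matrix
#'
#' Solves argmin_{w >= 0} ||S w - x||_2 on the genes shared between sample
#' and signature, then renormalizes w to sum to 1. An optional per-gene
#' median-matching alignment rescales each shared signature row so its
#' median matches the mixture median, a lightweight batch-correction
#' analogue for cross-platform inputs.
#'
#' @param expr expression matrix (genes x samples, linear scale) or a named
#'   numeric vector for a single sample
#' @param sig signature matrix, genes x cell types, non-negative
#' @param align_medians logical; apply the median-matching alignment
#' @return data.frame: sample, one column per cell type, residual (L2 norm
#'   of the fit residual on shared genes)
#' @export
deconvolve <- function(expr, sig, align_medians = FALSE) {
  if (is.null(dim(expr))) expr <- matrix(expr, ncol = 1,
                                         dimnames = list(names(expr), "sample1"))
  sig <- as.matrix(sig)
  if (any(sig < 0)) stop("signature matrix must be non-negative")
  shared <- intersect(rownames(expr), rownames(sig))
  if (length(shared) < ncol(sig)) {
    stop(sprintf("only %d shared gene(s) between sample and signature; need >= %d",
                 length(shared), ncol(sig)))
  }
  S <- sig[shared, , drop = FALSE]
  X <- expr[shared, , drop = FALSE]
  if (align_medians) {
    mix_med <- apply(X, 1, stats::median)
    sig_med <- apply(S, 1, stats::median)
    ok <- sig_med > 0
    S[ok, ] <- S[ok, ] * (mix_med[ok] + 1) / (sig_med[ok] + 1)
    ps_log("deconvolve: per-gene median-matching alignment applied",
           stage = "immune_deconv")
  }
  rows <- lapply(seq_len(ncol(X)), function(j) {
    fit <- pracma::lsqnonneg(S, X[, j])
    w <- fit$x
    if (sum(w) == 0) {
      ps_log(sprintf("deconvolve: sample '%s' has all-zero weights; uniform fractions reported",
                     colnames(X)[j]), stage = "immune_deconv")
      w <- rep(1, ncol(S))
    }
    frac <- w / sum(w)
    c(frac, residual = sqrt(sum((S %*% fit$x - X[, j])^2)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(colnames(S), "residual")
  cbind(data.frame(sample = colnames(X), stringsAsFactors = FALSE), out)
}

## Exact two-sided signed-rank p for small n (<= 25), zeros excluded;
## falls back to the normal approximation above that.
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    ## exact null of W+ over all 2^n sign assignments, by shift convolution;
    ## midranks from ties are handled on the doubled (integer) scale
    r2 <- round(2 * r)
    counts <- 1
    for (rr in r2) {
      counts <- c(counts, rep(0, rr)) + c(rep(0, rr), counts)
    }
    probs <- counts / sum(counts)
    w2 <- round(2 * w)
    support <- seq_along(probs) - 1
    p_low <- sum(probs[support <= w2])
    p_high <- sum(probs[support >= w2])
    min(1, 2 * min(p_low, p_high))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

star_label <- function(p) {
  if (is.na(p)) return("")
  if (p <= 0.001) return("***")
  if (p <= 0.01) return("**")
  if (p <= 0.05) return("*")
  ""
}

#' Compare cell-type fractions between paired groups
#'
#' Two-sided Wilcoxon signed-rank test on the per-patient
#' (recurrent - primary) fraction differences for each cell type, with the
#' exact small-sample null for n <= 25 and significance stars at
#' p <= 0.05 / 0.01 / 0.001. All-zero differences give p = 1 (logged).
#'
#' @param fractions data.frame from [deconvolve()]
#' @param pairing data.frame patient_id, primary, recurrent (sample ids)
#' @return data.frame cell_type, median_primary, median_recurrent,
#'   median_diff, p_value, stars
#' @export
compare_fractions <- function(fractions, pairing) {
  types <- setdiff(names(fractions), c("sample", "residual"))
  rownames(fractions) <- fractions$sample
  miss <- setdiff(c(pairing$primary, pairing$recurrent), fractions$sample)
  if (length(miss)) stop("paired sample(s) without fractions: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(types, function(ct) {
    prim <- fractions[pairing$primary, ct]
    rec <- fractions[pairing$recurrent, ct]
    d <- rec - prim
    if (all(d == 0)) {
      ps_log(sprintf("compare_fractions: all-zero differences for %s; p = 1", ct),
             stage = "immune_deconv")
      p <- 1
    } else {
      p <- signed_rank_p(d)
    }
    data.frame(cell_type = ct,
               median_primary = stats::median(prim),
               median_recurrent = stats::median(rec),
               median_diff = stats::median(d),
               p_value = p, stars = star_label(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
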