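## Paired differential expression between recurrent and primary tumors:
## per-patient log2 differences, a paired t-test (vectorized across genes),
## Benjamini-Hochberg q-values (Storey optional) and the DEG filter
## (q <= 0.05 and |fold change| >= 1.5 by default).

check_pairing <- function(mat, pairing) {
  need <- c("patient_id", "primary", "recurrent")
  if (!all(need %in% names(pairing))) {
    stop("pairing needs columns patient_id, primary, recurrent")
  }
  miss <- setdiff(c(pairing$primary, pairing$recurrent), colnames(mat))
  if (length(miss)) stop("paired sample(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pairing$patient_id)) stop("duplicated patient in pairing")
  pairing
}

## Per-patient log2(recurrent) - log2(primary), genes x patients.
paired_log2_diffs <- function(mat, pairing, offset = 1) {
  check_pairing(mat, pairing)
  if (identical(scale_tag(mat), "log2")) {
    lm2 <- mat
  } else {
    ps_log(sprintf("paired_log2_diffs: log2(x + %g) transform applied", offset),
           stage = "diffexpr")
    lm2 <- log2(mat + offset)
  }
  d <- lm2[, pairing$recurrent, drop = FALSE] - lm2[, pairing$primary, drop = FALSE]
  colnames(d) <- pairing$patient_id
  d
}

#' Paired log2 fold change
#'
#' Mean over patients of the per-patient log2(recurrent) - log2(primary)
#' difference. Non-log input is transformed as log2(x + offset) (logged).
#'
#' @param mat expression matrix
#' @param pairing data.frame patient_id, primary, recurrent (sample ids)
#' @param offset count offset used when `mat` is not already log2
#' @return named numeric vector, one log2 fold change per gene
#' @export
paired_log2fc <- function(mat, pairing, offset = 1) {
  rowMeans(paired_log2_diffs(mat, pairing, offset))
}

#' Paired two-sided t-test per gene
#'
#' One-sample t-test on the per-patient log2 differences, vectorized across
#' genes. Degenerate genes: all differences zero gives p = 1; identical
#' non-zero differences (zero variance) give the smallest representable
#' p-value, with a log record.
#'
#' @inheritParams paired_log2fc
#' @return named numeric vector of two-sided p-values
#' @export
paired_test <- function(mat, pairing, offset = 1) {
  d <- paired_log2_diffs(mat, pairing, offset)
  n <- ncol(d)
  if (n < 2) stop("paired test needs >= 2 patients")
  if (!all(is.finite(d))) stop("non-finite per-patient difference")
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  p <- rep(NA_real_, nrow(d))
  degen <- s == 0
  if (any(degen)) {
    zero_mean <- degen & m == 0
    p[zero_mean] <- 1
    p[degen & m != 0] <- .Machine$double.xmin
    if (any(degen & m != 0)) {
      ps_log(sprintf("paired_test: %d gene(s) with zero-variance non-zero differences; p set to smallest representable value",
                     sum(degen & m != 0)), stage = "diffexpr")
    }
  }
  ok <- !degen
  tt <- m[ok] / (s[ok] / sqrt(n))
  p[ok] <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
  stats::setNames(pmin(p, 1), rownames(d))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} m p_(j) / j, capped at 1 and
#' mapped back to the input order.
#'
#' @param p p-values in (0, 1]
#' @return q-values in input order
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values (lambda = 0.5)
#'
#' Estimates the null proportion pi0 = #\{p > lambda\} / (m (1 - lambda))
#' (capped at 1) and rescales the BH step-up quantities by pi0.
#'
#' @param p p-values in (0, 1]
#' @param lambda tuning parameter for the pi0 estimate
#' @return q-values in input order
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Build the differential-expression table
#'
#' @inheritParams paired_log2fc
#' @param q_method `"bh"` (default) or `"storey"`
#' @param q_cut,fc_cut DEG filter cutoffs (q inclusive; fold change on the
#'   linear scale, so the log2 criterion is |log2FC| >= log2(fc_cut))
#' @return data.frame gene, log2_fc, p_value, q_value, direction
#' @export
deg_table <- function(mat, pairing, q_method = c("bh", "storey"),
                      q_cut = 0.05, fc_cut = 1.5, offset = 1) {
  q_method <- match.arg(q_method)
  lfc <- paired_log2fc(mat, pairing, offset)
  p <- paired_test(mat, pairing, offset)
  q <- if (q_method == "bh") bh_qvalues(p) else storey_qvalues(p)
  pass <- q <= q_cut & abs(lfc) >= log2(fc_cut)
  data.frame(gene = names(lfc), log2_fc = unname(lfc),
             p_value = unname(p), q_value = unname(q),
             direction = ifelse(pass, ifelse(lfc > 0, "up", "down"), "none"),
             stringsAsFactors = FALSE)
}

#' Select differentially expressed genes
#'
#' A gene passes iff q <= `q_cut` and |log2FC| >= log2(`fc_cut`), both bounds
#' inclusive; the result is split by sign of the fold change.
#'
#' @param table DEG table from [deg_table()]
#' @param q_cut q-value cutoff
#' @param fc_cut linear fold-change cutoff (> 1)
#' @return list with `up` and `down` gene id vectors
#' @export
select_degs <- function(table, q_cut = 0.05, fc_cut = 1.5) {
  if (fc_cut <= 1) stop("fc_cut must exceed 1")
  pass <- table$q_value <= q_cut & abs(table$log2_fc) >= log2(fc_cut)
  list(up = table$gene[pass & table$log2_fc > 0],
       down = table$gene[pass & table$log2_fc < 0])
}
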