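## From trained pathway models to a ranked gene signature: Monte-Carlo
## Shapley attribution of the PR-class output to genes, the consensus rule
## over high-performing bootstraps (importance >= 0.01 in at least 50% of
## the models with test accuracy strictly above 0.80), the gene discriminant
## score across terms, and survival evaluation of the resulting signature.

#' Monte-Carlo Shapley values for pair instances
#'
#' Attribution of the model's PR-class probability to genes. The coalition
#' unit is the gene: both pair slots (the two samples' values for that gene)
#' toggle together. For each sampled permutation the genes are revealed in
#' order; features not yet revealed take background values, and every
#' coalition value is averaged over the full background set, which makes the
#' efficiency identity (values sum to f(x) minus the base value) hold
#' exactly by telescoping.
#'
#' @param net trained network
#' @param A,B instance features, n x genes (first/second pair member)
#' @param bg_A,bg_B background features, m x genes (e.g. training pairs)
#' @param n_perm permutations sampled per instance (>= 1)
#' @param seed RNG seed
#' @return list: `values` (n x genes matrix), `base_value` (mean model
#'   output over the background)
#' @export
shapley_values <- function(net, A, B, bg_A, bg_B, n_perm = 16, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(bg_A) < 1) stop("background set is empty")
  G <- ncol(A)
  n <- nrow(A)
  m <- nrow(bg_A)
  base_value <- mean(predict_pairs(net, bg_A, bg_B))
  values <- matrix(0, n, G, dimnames = list(NULL, colnames(A)))
  with_seed(seed, {
    for (i in seq_len(n)) {
      phi <- numeric(G)
      for (t in seq_len(n_perm)) {
        ord <- sample.int(G)
        ## rows (k, b): prefix of k revealed genes over background row b
        Abatch <- matrix(0, (G + 1) * m, G)
        Bbatch <- matrix(0, (G + 1) * m, G)
        for (b in seq_len(m)) {
          rows <- ((b - 1) * (G + 1) + 1):(b * (G + 1))
          Ab <- matrix(bg_A[b, ], G + 1, G, byrow = TRUE)
          Bb <- matrix(bg_B[b, ], G + 1, G, byrow = TRUE)
          for (k in seq_len(G)) {
            Ab[(k + 1):(G + 1), ord[k]] <- A[i, ord[k]]
            Bb[(k + 1):(G + 1), ord[k]] <- B[i, ord[k]]
          }
          Abatch[rows, ] <- Ab
          Bbatch[rows, ] <- Bb
        }
        f <- predict_pairs(net, Abatch, Bbatch)
        v <- rowMeans(matrix(f, G + 1, m))   # coalition value per prefix size
        phi[ord] <- phi[ord] + diff(v)
      }
      values[i, ] <- phi / n_perm
    }
  })
  list(values = values, base_value = base_value)
}

#' Aggregate per-instance Shapley values to one importance per gene
#'
#' Mean over instances of the absolute Shapley value (sign-robust scalar the
#' consensus threshold is applied to).
#'
#' @param values n x genes matrix from [shapley_values()]
#' @return named numeric vector, one importance per gene
#' @export
aggregate_importance <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (nrow(values) < 1) stop("need >= 1 instance")
  colMeans(abs(values))
}

#' Consensus gene selection for one term
#'
#' A bootstrap model is high-performing if its test accuracy is strictly
#' greater than `acc_cut`. With H high performers, a gene is selected iff
#' its importance reaches `shap_cut` in at least ceiling(`frac` * H) of
#' them; H = 0 selects nothing.
#'
#' @param accuracies per-bootstrap test accuracies
#' @param importances list (one element per bootstrap) of named importance
#'   vectors from [aggregate_importance()]
#' @param acc_cut,shap_cut,frac the consensus rule constants
#' @return list: `H`, `required`, `table` (data.frame gene, pass_count,
#'   mean_importance, selected)
#' @export
consensus_select <- function(accuracies, importances, acc_cut = 0.80,
                             shap_cut = 0.01, frac = 0.50) {
  stopifnot(length(accuracies) == length(importances))
  high <- which(accuracies > acc_cut)
  H <- length(high)
  required <- if (H > 0) as.integer(ceiling(frac * H)) else NA_integer_
  genes <- unique(unlist(lapply(importances, names)))
  if (H == 0 || !length(genes)) {
    return(list(H = H, required = required,
                table = data.frame(gene = genes,
                                   pass_count = integer(length(genes)),
                                   mean_importance = numeric(length(genes)),
                                   selected = logical(length(genes)))))
  }
  imp_mat <- vapply(importances[high], function(v) v[genes], numeric(length(genes)))
  imp_mat <- matrix(imp_mat, nrow = length(genes),
                    dimnames = list(genes, NULL))
  imp_mat[is.na(imp_mat)] <- 0
  pass <- rowSums(imp_mat >= shap_cut)
  list(H = H, required = required,
       table = data.frame(gene = genes,
                          pass_count = as.integer(pass),
                          mean_importance = rowMeans(imp_mat),
                          selected = pass >= required,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Gene discriminant scores across terms
#'
#' The discriminant score of a gene is the number of distinct terms
#' (pathways plus GO terms) in which it passed the consensus rule. Ranked
#' descending, ties broken by mean importance across the selecting models,
#' then gene id.
#'
#' @param selections data.frame with one row per (term, gene) selection:
#'   columns term_id, category, gene, mean_importance
#' @param top_n signature size returned
#' @return list: `table` (all scored genes: gene, score, pathway_count,
#'   go_count, mean_importance, rank), `signature` (top_n gene ids)
#' @export
discriminant_scores <- function(selections, top_n = 20) {
  if (!nrow(selections)) stop("no consensus selections to score")
  genes <- unique(selections$gene)
  rows <- lapply(genes, function(g) {
    sub <- selections[selections$gene == g, , drop = FALSE]
    data.frame(gene = g,
               score = length(unique(sub$term_id)),
               pathway_count = length(unique(sub$term_id[sub$category == "pathway"])),
               go_count = length(unique(sub$term_id[sub$category == "go_bp"])),
               mean_importance = mean(sub$mean_importance),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, -tab$mean_importance, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab, signature = utils::head(tab$gene, top_n))
}

#' Run Shapley consensus over the bootstraps of each curated term
#'
#' For every term, computes importances on the test pairs of each
#' high-performing bootstrap (background = that bootstrap's training pairs,
#' subsampled) and applies the consensus rule.
#'
#' @param term_runs named list: term_id -> output of [run_bootstraps()]
#' @param categories named character vector term_id -> category
#' @param acc_cut,shap_cut,frac consensus constants
#' @param n_perm,max_background,max_instances Shapley estimator size knobs
#' @param seed base seed for the Shapley sampling
#' @return list: `selections` (data.frame term_id, category, gene,
#'   pass_count, H, mean_importance), `per_term` (consensus_select outputs)
#' @export
consensus_over_terms <- function(term_runs, categories, acc_cut = 0.80,
                                 shap_cut = 0.01, frac = 0.50, n_perm = 8,
                                 max_background = 8, max_instances = 16,
                                 seed = 0) {
  per_term <- list()
  sel_rows <- list()
  for (term in names(term_runs)) {
    run <- term_runs[[term]]
    accs <- vapply(run$results, function(r) unname(r$metrics["accuracy"]), 0)
    imps <- vector("list", length(run$results))
    for (b in seq_along(run$results)) {
      if (accs[b] <= acc_cut) {
        imps[[b]] <- stats::setNames(numeric(0), character(0))
        next
      }
      r <- run$results[[b]]
      fte <- pair_features(r$expr_z, r$split$test)
      ftr <- pair_features(r$expr_z, r$split$train)
      sub_seed <- seed + 1000L * match(term, names(term_runs)) + b
      with_seed(sub_seed, {
        bg_idx <- sample(nrow(ftr$A), min(max_background, nrow(ftr$A)))
        in_idx <- sample(nrow(fte$A), min(max_instances, nrow(fte$A)))
      })
      sh <- shapley_values(r$model, fte$A[in_idx, , drop = FALSE],
                           fte$B[in_idx, , drop = FALSE],
                           ftr$A[bg_idx, , drop = FALSE],
                           ftr$B[bg_idx, , drop = FALSE],
                           n_perm = n_perm, seed = sub_seed)
      imps[[b]] <- aggregate_importance(sh$values)
    }
    cs <- consensus_select(accs, imps, acc_cut, shap_cut, frac)
    per_term[[term]] <- cs
    sel <- cs$table[cs$table$selected, , drop = FALSE]
    if (nrow(sel)) {
      sel_rows[[term]] <- data.frame(term_id = term,
                                     category = unname(categories[term]),
                                     gene = sel$gene,
                                     pass_count = sel$pass_count,
                                     H = cs$H,
                                     mean_importance = sel$mean_importance,
                                     stringsAsFactors = FALSE)
    }
  }
  selections <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(term_id = character(0), category = character(0),
               gene = character(0), pass_count = integer(0), H = integer(0),
               mean_importance = numeric(0))
  rownames(selections) <- NULL
  list(selections = selections, per_term = per_term)
}

#' Altered/unaltered grouping by signature z-scores
#'
#' Standardizes each signature gene across the cohort (sample mean/SD) and
#' labels a sample altered iff any signature gene exceeds `z_cut` (strict)
#' in that sample. Signature genes absent from the matrix are logged and
#' skipped.
#'
#' @param mat expression matrix (genes x samples)
#' @param signature character vector of signature gene ids
#' @param z_cut z-score threshold (strict inequality)
#' @return named character vector sample -> "altered"/"unaltered"
#' @export
altered_grouping <- function(mat, signature, z_cut = 2) {
  present <- intersect(signature, rownames(mat))
  absent <- setdiff(signature, present)
  if (length(absent)) {
    ps_log(sprintf("altered_grouping: %d signature gene(s) absent, skipped: %s",
                   length(absent), paste(absent, collapse = ", ")),
           stage = "signature_consensus")
  }
  if (!length(present)) stop("no signature gene present in matrix")
  sub <- mat[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1, stats::sd)
  sd_[sd_ == 0] <- Inf          # constant gene can never exceed the cutoff
  z <- (sub - mu) / sd_
  altered <- apply(z, 2, function(col) any(col > z_cut))
  stats::setNames(ifelse(altered, "altered", "unaltered"), colnames(mat))
}

#' Kaplan-Meier comparison of altered vs unaltered samples
#'
#' Product-limit curves per group, median survival (smallest time with
#' survival <= 0.5; reported as NA when the curve never falls that far) and
#' the two-group log-rank test. With zero events overall the log-rank
#' statistic is undefined and reported as NA (logged).
#'
#' @param surv data.frame: time (months, > 0), event (0/1), group
#' @return list: `fit` (survfit object), `summary` (data.frame group, n,
#'   events, median_months), `logrank_chisq`, `logrank_p`
#' @export
km_analysis <- function(surv) {
  stopifnot(all(c("time", "event", "group") %in% names(surv)))
  if (any(surv$time <= 0) || any(!is.finite(surv$time))) {
    stop("survival times must be positive and finite")
  }
  groups <- unique(surv$group)
  if (length(groups) != 2) stop("need exactly 2 non-empty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = surv)
  st <- summary(fit)$table
  smry <- data.frame(group = sub("^group=", "", rownames(st)),
                     n = st[, "records"], events = st[, "events"],
                     median_months = st[, "median"],
                     row.names = NULL, stringsAsFactors = FALSE)
  if (sum(surv$event) == 0) {
    ps_log("km_analysis: zero events; log-rank undefined", stage = "signature_consensus")
    chisq <- NA_real_; p <- NA_real_
  } else {
    sd_ <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ group,
                                       data = surv),
                    error = function(e) NULL)
    if (is.null(sd_)) {
      chisq <- NA_real_; p <- NA_real_
    } else {
      chisq <- sd_$chisq
      p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    }
  }
  list(fit = fit, summary = smry, logrank_chisq = chisq, logrank_p = p)
}
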