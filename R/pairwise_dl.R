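## The pairwise pathway-centric classifier. Each instance is a pair of
## samples restricted to one pathway's genes: a genes x 2 patch whose label
## says whether the pair is primary-primary (PP, 0) or primary-recurrent
## (PR, 1). The network is the printed architecture: 16 convolution filters
## with a 1x2 kernel spanning the two samples of each gene (so each filter
## learns one per-gene pair-contrast), the flattened filter maps feeding
## dense layers of 32 and 16 ReLU units, and a 2-way softmax output trained
## with cross-entropy under Adagrad. Implemented directly in base R matrix
## algebra; the models are tiny (tens of genes) and train in seconds.

#' Per-sample per-pathway standardization
#'
#' Restricts the matrix to the gene set and scales each sample's vector over
#' those genes to mean 0, SD 1 (population SD, ddof = 0), so models see only
#' relative expression patterns within the pathway. Constant vectors map to
#' all zeros with a log record.
#'
#' @param mat expression matrix (genes x samples)
#' @param gene_set character vector of pathway genes (>= 2 present in `mat`)
#' @return standardized sub-matrix, genes x samples
#' @export
pathway_znorm <- function(mat, gene_set) {
  genes <- intersect(gene_set, rownames(mat))
  if (length(genes) < 2) {
    stop(sprintf("only %d gene(s) of the set present; need >= 2", length(genes)))
  }
  sub <- mat[genes, , drop = FALSE]
  mu <- colMeans(sub)
  centered <- sweep(sub, 2, mu, `-`)
  sdp <- sqrt(colMeans(centered^2))    # population SD
  const <- sdp == 0
  if (any(const)) {
    ps_log(sprintf("pathway_znorm: %d constant sample vector(s) set to zero",
                   sum(const)), stage = "pairwise_dl")
    sdp[const] <- 1
  }
  sweep(centered, 2, sdp, `/`)
}

#' Build the full pair set
#'
#' All unordered primary-primary pairs (label 0) and all primary x recurrent
#' pairs (label 1, ordered primary then recurrent).
#'
#' @param primary_ids,recurrent_ids disjoint sample id vectors
#' @return data.frame sample_a, sample_b, label
#' @export
build_pairs <- function(primary_ids, recurrent_ids) {
  if (length(intersect(primary_ids, recurrent_ids))) {
    stop("primary and recurrent id lists overlap")
  }
  if (length(recurrent_ids) == 0) stop("no recurrent samples: positive class empty")
  if (length(primary_ids) < 2) stop("need >= 2 primary samples for PP pairs")
  pp <- utils::combn(primary_ids, 2)
  pp_df <- data.frame(sample_a = pp[1, ], sample_b = pp[2, ], label = 0L,
                      stringsAsFactors = FALSE)
  pr_df <- expand.grid(sample_a = primary_ids, sample_b = recurrent_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pr_df$label <- 1L
  rbind(pp_df, pr_df)
}

#' Sample-level split, then pairing within each split
#'
#' Samples (not pairs) are partitioned into train and test, stratified by
#' tissue class, and pairs are formed within each split, so no sample leaks
#' across the boundary.
#'
#' @param primary_ids,recurrent_ids disjoint sample id vectors
#' @param test_fraction fraction of samples held out (0 < f < 1)
#' @param seed RNG seed for the partition
#' @return list: `train`, `test` (pair data.frames), `train_samples`,
#'   `test_samples`
#' @export
split_then_pair <- function(primary_ids, recurrent_ids, test_fraction = 0.2,
                            seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)")
  }
  if (length(recurrent_ids) < 2) {
    stop("need >= 2 recurrent samples so both splits contain the positive class")
  }
  with_seed(seed, {
    n_test_p <- max(2, round(test_fraction * length(primary_ids)))
    n_test_r <- max(1, round(test_fraction * length(recurrent_ids)))
    if (n_test_p >= length(primary_ids) - 1 || n_test_r >= length(recurrent_ids)) {
      stop("split leaves a side without both classes; adjust test_fraction")
    }
    test_p <- sample(primary_ids, n_test_p)
    test_r <- sample(recurrent_ids, n_test_r)
  })
  train_p <- setdiff(primary_ids, test_p)
  train_r <- setdiff(recurrent_ids, test_r)
  list(train = build_pairs(train_p, train_r),
       test = build_pairs(test_p, test_r),
       train_samples = c(train_p, train_r),
       test_samples = c(test_p, test_r))
}

#' Model hyper-parameters
#'
#' Architecture constants default to the printed design (16 conv filters,
#' dense 32/16); training hyper-parameters are configurable.
#'
#' @param n_genes pathway size (input rows)
#' @param conv_filters,dense_units architecture
#' @param epochs,learning_rate,batch_size Adagrad training loop
#' @param balance_ratio PP:PR ratio after per-epoch subsampling of the
#'   majority PP class (1 = balanced)
#' @return list of class `model_spec`
#' @export
model_spec <- function(n_genes, conv_filters = 16, dense_units = c(32, 16),
                       epochs = 100, learning_rate = 0.05, batch_size = 32,
                       balance_ratio = 1) {
  stopifnot(n_genes >= 2, conv_filters >= 1, length(dense_units) == 2,
            epochs >= 1, learning_rate > 0, batch_size >= 1, balance_ratio > 0)
  structure(list(n_genes = n_genes, conv_filters = conv_filters,
                 dense_units = dense_units, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 balance_ratio = balance_ratio),
            class = "model_spec")
}

## He-style initialization, deterministic under the caller's RNG state.
init_network <- function(spec) {
  G <- spec$n_genes; f <- spec$conv_filters
  d1 <- spec$dense_units[1]; d2 <- spec$dense_units[2]
  rn <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(Wc = rn(f, 2, 2), bc = numeric(f),
       W1 = rn(G * f, d1, G * f), b1 = numeric(d1),
       W2 = rn(d1, d2, d1), b2 = numeric(d2),
       W3 = rn(d2, 2, d2), b3 = numeric(2),
       spec = spec)
}

## Forward pass on a batch. A, B: n x G matrices (first/second pair sample).
nn_forward <- function(net, A, B) {
  spec <- net$spec
  G <- spec$n_genes; f <- spec$conv_filters
  n <- nrow(A)
  Zpre <- matrix(0, n, G * f)
  for (k in seq_len(f)) {
    Zpre[, ((k - 1) * G + 1):(k * G)] <-
      net$Wc[k, 1] * A + net$Wc[k, 2] * B + net$bc[k]
  }
  C <- pmax(Zpre, 0)
  H1pre <- C %*% net$W1 + rep(net$b1, each = n)
  H1 <- pmax(H1pre, 0)
  H2pre <- H1 %*% net$W2 + rep(net$b2, each = n)
  H2 <- pmax(H2pre, 0)
  logits <- H2 %*% net$W3 + rep(net$b3, each = n)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, Zpre = Zpre, C = C, H1pre = H1pre, H1 = H1,
       H2pre = H2pre, H2 = H2)
}

## Gradient of mean cross-entropy w.r.t. every parameter.
nn_backward <- function(net, A, B, y, fw) {
  spec <- net$spec
  G <- spec$n_genes; f <- spec$conv_filters
  n <- nrow(A)
  Y <- cbind(1 - y, y)
  dL <- (fw$probs - Y) / n
  gW3 <- crossprod(fw$H2, dL); gb3 <- colSums(dL)
  dH2 <- (dL %*% t(net$W3)) * (fw$H2pre > 0)
  gW2 <- crossprod(fw$H1, dH2); gb2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(net$W2)) * (fw$H1pre > 0)
  gW1 <- crossprod(fw$C, dH1); gb1 <- colSums(dH1)
  dC <- (dH1 %*% t(net$W1)) * (fw$Zpre > 0)
  gWc <- matrix(0, f, 2); gbc <- numeric(f)
  for (k in seq_len(f)) {
    blk <- dC[, ((k - 1) * G + 1):(k * G), drop = FALSE]
    gWc[k, 1] <- sum(blk * A)
    gWc[k, 2] <- sum(blk * B)
    gbc[k] <- sum(blk)
  }
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3)
}

## Assemble n x G feature matrices for a pair table from the standardized
## pathway sub-matrix.
pair_features <- function(expr_z, pairs) {
  list(A = t(expr_z[, pairs$sample_a, drop = FALSE]),
       B = t(expr_z[, pairs$sample_b, drop = FALSE]))
}

#' Predict PR-class probabilities for pair features
#'
#' @param net trained network (from [train_pathway_model()], element `model`)
#' @param A,B n x genes matrices: expression of the first/second pair member
#' @return numeric vector of P(PR) per pair
#' @export
predict_pairs <- function(net, A, B) {
  nn_forward(net, A, B)$probs[, 2]
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  ratio <- function(num, den, what) {
    if (den == 0) {
      ps_log(sprintf("metrics: %s undefined (zero denominator); recorded missing",
                     what), stage = "pairwise_dl")
      return(NA_real_)
    }
    num / den
  }
  list(confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
       accuracy = (tp + tn) / length(truth),
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       precision = ratio(tp, tp + fp, "precision"))
}

#' Train one bootstrap of a pathway model
#'
#' Trains the pairwise convolutional classifier on the train pairs (with
#' per-epoch random subsampling of the majority PP class to the configured
#' ratio) and evaluates on the test pairs. All randomness derives from
#' `seed`; the same seed reproduces identical metrics.
#'
#' @param expr_z standardized pathway sub-matrix from [pathway_znorm()]
#' @param split list with `train`/`test` pair tables from [split_then_pair()]
#' @param spec a [model_spec()]
#' @param seed integer seed
#' @return list: `model`, `metrics` (accuracy/sensitivity/specificity/
#'   precision), `confusion`, `seed`
#' @export
train_pathway_model <- function(expr_z, split, spec = NULL, seed = 1) {
  if (is.null(spec)) spec <- model_spec(nrow(expr_z))
  if (spec$n_genes != nrow(expr_z)) stop("spec$n_genes does not match matrix")
  train <- split$train; test <- split$test
  if (!any(train$label == 1) || !any(train$label == 0) ||
      !any(test$label == 1) || !any(test$label == 0)) {
    stop("both classes must be present in train and test pairs")
  }
  ftr <- pair_features(expr_z, train)
  fte <- pair_features(expr_z, test)
  pp_idx <- which(train$label == 0)
  pr_idx <- which(train$label == 1)
  n_pp_keep <- min(length(pp_idx),
                   max(1, round(spec$balance_ratio * length(pr_idx))))
  net <- NULL
  with_seed(seed, {
    net <- init_network(spec)
    acc_state <- lapply(net[names(net) != "spec"], function(w) w * 0)
    eps <- 1e-8
    for (epoch in seq_len(spec$epochs)) {
      sel <- c(sample(pp_idx, n_pp_keep), pr_idx)
      sel <- sample(sel)
      for (start in seq(1, length(sel), by = spec$batch_size)) {
        idx <- sel[start:min(start + spec$batch_size - 1, length(sel))]
        A <- ftr$A[idx, , drop = FALSE]; B <- ftr$B[idx, , drop = FALSE]
        y <- train$label[idx]
        fw <- nn_forward(net, A, B)
        loss <- -mean(log(pmax(fw$probs[cbind(seq_along(y), y + 1)], 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch starting %d", epoch, start))
        }
        gr <- nn_backward(net, A, B, y, fw)
        for (nm in names(gr)) {
          acc_state[[nm]] <- acc_state[[nm]] + gr[[nm]]^2
          net[[nm]] <- net[[nm]] -
            spec$learning_rate * gr[[nm]] / (sqrt(acc_state[[nm]]) + eps)
        }
      }
    }
  })
  prob <- predict_pairs(net, fte$A, fte$B)
  pred <- as.integer(prob > 0.5)
  cm <- confusion_metrics(test$label, pred)
  list(model = net,
       metrics = c(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                   specificity = cm$specificity, precision = cm$precision),
       confusion = cm$confusion,
       seed = seed)
}

#' Run the bootstrap loop for one term
#'
#' "Bootstrapping" here is repeated random re-partitioning of the samples
#' into train and test (not resampling with replacement): bootstrap b uses
#' seed `base_seed + b` for both the partition and the training loop.
#'
#' @param mat expression matrix (cohort-merged, normalized)
#' @param gene_set the term's feature genes
#' @param primary_ids,recurrent_ids sample ids by class
#' @param n_boot number of bootstraps
#' @param base_seed integer; bootstrap b uses base_seed + b
#' @param test_fraction held-out sample fraction
#' @param spec optional [model_spec()] override
#' @return list: `results` (per-bootstrap list from
#'   [train_pathway_model()], each with the realized split attached),
#'   `summary` (median metrics across bootstraps)
#' @export
run_bootstraps <- function(mat, gene_set, primary_ids, recurrent_ids,
                           n_boot = 10, base_seed = 0, test_fraction = 0.2,
                           spec = NULL) {
  expr_z <- pathway_znorm(mat, gene_set)
  if (is.null(spec)) spec <- model_spec(nrow(expr_z))
  results <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    seed_b <- base_seed + b
    split <- split_then_pair(primary_ids, recurrent_ids, test_fraction, seed_b)
    res <- tryCatch(
      train_pathway_model(expr_z, split, spec, seed_b),
      error = function(e) stop(sprintf("bootstrap %d failed: %s", b, conditionMessage(e)))
    )
    res$split <- split
    res$expr_z <- expr_z
    results[[b]] <- res
  }
  list(results = results, summary = metric_summary(results))
}

#' Median metrics across bootstrap results
#'
#' Undefined ratios (zero-denominator sensitivities etc.) are missing values
#' and are excluded from the medians.
#'
#' @param results list of results from [train_pathway_model()], possibly
#'   pooled across terms
#' @return named numeric vector of medians (accuracy, sensitivity,
#'   specificity, precision)
#' @export
metric_summary <- function(results) {
  if (!length(results)) stop("no results to summarize")
  met <- do.call(rbind, lapply(results, `[[`, "metrics"))
  apply(met, 2, stats::median, na.rm = TRUE)
}
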