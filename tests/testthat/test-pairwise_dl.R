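test_that("per-sample per-pathway standardization hits its post-condition", {
  set.seed(71)
  mat <- matrix(rlnorm(30 * 8, 3, 1), 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  z <- pathway_znorm(mat, rownames(mat)[1:12])
  expect_equal(dim(z), c(12, 8))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(sqrt(colMeans(z^2)) - 1)), 1e-12)

  ## the stated 3-point example with population SD
  toy <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(as.numeric(pathway_znorm(toy, c("a", "b", "c"))),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)))

  ## scale invariance per sample
  mat10 <- mat
  mat10[, 3] <- mat10[, 3] * 10
  expect_equal(pathway_znorm(mat10, rownames(mat))[, 3],
               pathway_znorm(mat, rownames(mat))[, 3])

  ## constant sample maps to zeros with a log record
  matc <- mat
  matc[1:12, 5] <- 7
  got <- ps_log_collect(pathway_znorm(matc, rownames(mat)[1:12]))
  expect_equal(unname(got$value[, 5]), rep(0, 12))
  expect_match(got$log, "constant", all = FALSE)

  expect_error(pathway_znorm(mat, c("g01", "absent")), ">= 2")
})

test_that("pair construction counts PP and PR pairs exactly", {
  p3 <- build_pairs(c("a", "b", "c"), c("x", "y"))
  expect_equal(sum(p3$label == 0), 3)
  expect_equal(sum(p3$label == 1), 6)
  ## PR pairs are ordered (primary, recurrent)
  expect_true(all(p3$sample_b[p3$label == 1] %in% c("x", "y")))

  big <- build_pairs(sprintf("p%03d", 1:367), sprintf("r%d", 1:7))
  expect_equal(sum(big$label == 0), choose(367, 2))  # 67,161
  expect_equal(sum(big$label == 1), 367 * 7)         # 2,569

  expect_error(build_pairs(c("a", "b"), character(0)), "positive class")
  expect_error(build_pairs(c("a", "b"), c("b", "c")), "overlap")
})

test_that("sample-level splitting prevents pair leakage and is seeded", {
  prim <- sprintf("p%02d", 1:10)
  rec <- sprintf("r%d", 1:4)
  sp <- split_then_pair(prim, rec, test_fraction = 0.5, seed = 7)
  expect_length(intersect(sp$train_samples, sp$test_samples), 0)
  expect_length(intersect(unlist(sp$train[1:2]), unlist(sp$test[1:2])), 0)

  ## realized pair counts match the closed forms
  for (side in c("train", "test")) {
    ids <- sp[[paste0(side, "_samples")]]
    P <- sum(ids %in% prim); R <- sum(ids %in% rec)
    expect_equal(sum(sp[[side]]$label == 0), choose(P, 2))
    expect_equal(sum(sp[[side]]$label == 1), P * R)
  }

  sp2 <- split_then_pair(prim, rec, test_fraction = 0.5, seed = 7)
  expect_identical(sp, sp2)
  sp3 <- split_then_pair(prim, rec, test_fraction = 0.5, seed = 8)
  expect_false(identical(sp$test_samples, sp3$test_samples))

  expect_error(split_then_pair(prim, "r1", 0.5, 1), ">= 2 recurrent")
  expect_error(split_then_pair(prim, rec, 1.2, 1), "0, 1")
})

test_that("the pairwise classifier separates planted signal and is deterministic", {
  cohort <- make_signal_cohort(n_genes = 20, n_signal = 6, shift = 3, seed = 72)
  z <- pathway_znorm(cohort$mat, rownames(cohort$mat))
  sp <- split_then_pair(cohort$primary, cohort$recurrent, 0.25, seed = 73)
  res <- train_pathway_model(z, sp, model_spec(20), seed = 74)
  expect_gte(res$metrics[["accuracy"]], 0.95)

  res2 <- train_pathway_model(z, sp, model_spec(20), seed = 74)
  expect_identical(res$metrics, res2$metrics)

  ## permuted labels leave the model near chance
  set.seed(75)
  null_mat <- cohort$mat
  null_mat[] <- rnorm(length(null_mat))
  zn <- pathway_znorm(null_mat, rownames(null_mat))
  accs <- vapply(1:4, function(b) {
    spb <- split_then_pair(cohort$primary, cohort$recurrent, 0.25, seed = 80 + b)
    train_pathway_model(zn, spb, model_spec(20), seed = 80 + b)$metrics[["accuracy"]]
  }, 0)
  expect_lt(abs(median(accs) - 0.5), 0.2)

  bad <- sp
  bad$train <- bad$train[bad$train$label == 0, ]
  expect_error(train_pathway_model(z, bad, model_spec(20), seed = 1),
               "both classes")
})

test_that("confusion-matrix metrics follow their definitions", {
  truth <- c(rep(1, 10), rep(0, 28))
  pred <- c(rep(1, 9), 0, rep(0, 27), 1)     # TP 9, FN 1, TN 27, FP 1
  cm <- pathsig:::confusion_metrics(truth, pred)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 27 / 28)
  expect_equal(cm$precision, 0.9)

  perfect <- pathsig:::confusion_metrics(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "precision")]), c(accuracy = 1, sensitivity = 1,
                                                  specificity = 1, precision = 1))

  ## no positive predictions: precision missing, not zero
  none <- suppressMessages(pathsig:::confusion_metrics(truth, rep(0, 38)))
  expect_true(is.na(none$precision))
  expect_equal(none$specificity, 1)
})

test_that("the bootstrap loop re-partitions with derived seeds and summarizes", {
  cohort <- make_signal_cohort(n_genes = 12, n_primary = 12, n_recurrent = 6,
                               n_signal = 4, shift = 3, seed = 76)
  run <- run_bootstraps(cohort$mat, rownames(cohort$mat), cohort$primary,
                        cohort$recurrent, n_boot = 3, base_seed = 100,
                        test_fraction = 0.3,
                        spec = model_spec(12, epochs = 40))
  expect_length(run$results, 3)
  expect_equal(vapply(run$results, `[[`, 0, "seed"), c(101, 102, 103))
  met <- do.call(rbind, lapply(run$results, `[[`, "metrics"))
  expect_equal(run$summary[["accuracy"]], median(met[, "accuracy"]))
  ## split differs across bootstraps
  expect_false(identical(run$results[[1]]$split$test_samples,
                         run$results[[2]]$split$test_samples))
  expect_error(metric_summary(list()), "no results")
})
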