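test_that("Shapley values vanish for ignored inputs and satisfy efficiency", {
  G <- 4
  net <- linear_gene1_net(G)
  set.seed(81)
  xA <- matrix(rnorm(2 * G), 2, G)
  xB <- matrix(rnorm(2 * G), 2, G)
  bgA <- matrix(rnorm(5 * G), 5, G)
  bgB <- matrix(rnorm(5 * G), 5, G)
  sh <- shapley_values(net, xA, xB, bgA, bgB, n_perm = 6, seed = 82)
  ## the model reads only gene 1: every other gene gets exactly zero
  expect_equal(unname(sh$values[, 2:G]), matrix(0, 2, G - 1))
  ## efficiency: rows sum to f(x) - base, exactly by construction
  fx <- predict_pairs(net, xA, xB)
  expect_equal(rowSums(sh$values), fx - sh$base_value, tolerance = 1e-12)

  ## a constant model attributes nothing
  const_net <- net
  const_net$Wc[] <- 0
  shc <- shapley_values(const_net, xA, xB, bgA, bgB, n_perm = 3, seed = 83)
  expect_equal(unname(shc$values), matrix(0, 2, G))

  expect_error(shapley_values(net, xA, xB, bgA, bgB, n_perm = 0), "n_perm")
})

test_that("sampled Shapley matches exact enumeration on a trained model", {
  cohort <- make_signal_cohort(n_genes = 6, n_primary = 10, n_recurrent = 6,
                               n_signal = 2, shift = 3, seed = 84)
  z <- pathway_znorm(cohort$mat, rownames(cohort$mat))
  sp <- split_then_pair(cohort$primary, cohort$recurrent, 0.3, seed = 85)
  res <- train_pathway_model(z, sp, model_spec(6, epochs = 60), seed = 85)
  fte <- pathsig:::pair_features(z, sp$test)
  ftr <- pathsig:::pair_features(z, sp$train)
  bgA <- ftr$A[1:6, , drop = FALSE]; bgB <- ftr$B[1:6, , drop = FALSE]
  for (i in 1:2) {
    est <- shapley_values(res$model, fte$A[i, , drop = FALSE],
                          fte$B[i, , drop = FALSE], bgA, bgB,
                          n_perm = 1000, seed = 86 + i)
    exact <- exact_shapley(res$model, fte$A[i, ], fte$B[i, ], bgA, bgB)
    expect_lt(max(abs(est$values[1, ] - exact)), 0.01)
  }
})

test_that("importance aggregation is the mean absolute value", {
  expect_equal(aggregate_importance(matrix(c(0.02, -0.02), 2, 1)), 0.02)
  one <- matrix(-0.3, 1, 1, dimnames = list(NULL, "g1"))
  expect_equal(aggregate_importance(one), c(g1 = 0.3))
  set.seed(87)
  vals <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, sprintf("g%d", 1:5)))
  expect_equal(aggregate_importance(vals), colMeans(abs(vals)))
})

test_that("the consensus rule reproduces the 8-of-10 worked example", {
  genes <- c("IL6", "TNF", "CD86")
  mk_imp <- function(il6, tnf, cd86) setNames(c(il6, tnf, cd86), genes)
  ## 10 bootstraps, 8 with accuracy > 0.80 (one at exactly 0.80 must not count)
  accs <- c(0.95, 0.90, 0.85, 0.88, 0.92, 0.81, 0.83, 0.86, 0.80, 0.10)
  imps <- c(replicate(5, mk_imp(0.05, 0.005, 0.02), simplify = FALSE),
            replicate(3, mk_imp(0.05, 0.005, 0.002), simplify = FALSE),
            replicate(2, mk_imp(0.5, 0.5, 0.5), simplify = FALSE))
  cs <- consensus_select(accs, imps)
  expect_equal(cs$H, 8)
  expect_equal(cs$required, 4L)         # ceiling(0.5 * 8)
  tab <- cs$table
  expect_true(tab$selected[tab$gene == "IL6"])    # 8 of 8 passes
  expect_false(tab$selected[tab$gene == "TNF"])   # importance below 0.01
  expect_true(tab$selected[tab$gene == "CD86"])   # 5 of 8 passes
  ## the two non-high-performers never contribute despite huge importances
  expect_equal(tab$pass_count[tab$gene == "TNF"], 0L)

  ## H = 7 requires ceiling(3.5) = 4
  cs7 <- consensus_select(accs[1:7], imps[1:7])
  expect_equal(cs7$H, 7)
  expect_equal(cs7$required, 4L)

  ## H = 0: nothing selected
  cs0 <- consensus_select(c(0.5, 0.80), imps[1:2])
  expect_equal(cs0$H, 0)
  expect_false(any(cs0$table$selected))

  ## monotonicity: raising shap_cut or frac never adds a gene
  sel_base <- cs$table$gene[cs$table$selected]
  for (args in list(list(shap_cut = 0.03), list(frac = 0.8))) {
    cs_t <- do.call(consensus_select, c(list(accs, imps), args))
    expect_true(all(cs_t$table$gene[cs_t$table$selected] %in% sel_base))
  }
})

test_that("discriminant scores count terms and break ties by importance", {
  sel <- data.frame(
    term_id = c("P1", "P2", "P3", "G1", "G2", "P1", "P2", "P3", "G1"),
    category = c("pathway", "pathway", "pathway", "go_bp", "go_bp",
                 "pathway", "pathway", "pathway", "go_bp"),
    gene = c(rep("IL6", 5), rep("TNF", 4)),
    pass_count = 4, H = 8,
    mean_importance = c(rep(0.05, 5), rep(0.2, 4)))
  ds <- discriminant_scores(sel, top_n = 2)
  tab <- ds$table
  expect_equal(tab$score[tab$gene == "IL6"], 5)    # 3 pathways + 2 GO terms
  expect_equal(tab$pathway_count[tab$gene == "IL6"], 3)
  expect_equal(tab$go_count[tab$gene == "IL6"], 2)
  expect_identical(ds$signature, c("IL6", "TNF"))

  ## tie at equal score resolved by mean importance
  tie <- sel[sel$gene == "IL6", ]
  tie2 <- tie; tie2$gene <- "OSM"; tie2$mean_importance <- 0.9
  ds2 <- discriminant_scores(rbind(tie, tie2), top_n = 2)
  expect_identical(ds2$table$gene, c("OSM", "IL6"))
  expect_error(discriminant_scores(sel[0, ]), "no consensus")
})

test_that("altered grouping uses a strict z > 2 on any signature gene", {
  ## evenly spaced rows: max |z| is (1 - 0)/sd(seq) ~ 1.69, below the cutoff
  mat <- matrix(rep(seq(-1, 1, length.out = 50), each = 5), 5, 50,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:50)))
  g0 <- altered_grouping(mat, rownames(mat))
  expect_true(all(g0 == "unaltered"))

  ## one far outlier in one gene marks exactly that sample altered
  mat2 <- mat
  mat2[2, "s07"] <- 100
  g1 <- altered_grouping(mat2, rownames(mat2))
  expect_identical(unname(g1["s07"]), "altered")
  expect_equal(sum(g1 == "altered"), 1)

  ## z exactly at the cutoff stays unaltered (strict inequality)
  z <- (mat[3, ] - mean(mat[3, ])) / sd(mat[3, ])
  expect_identical(unname(altered_grouping(mat, "g3",
                                           z_cut = max(z))[which.max(z)]),
                   "unaltered")

  got <- ps_log_collect(altered_grouping(mat, c("g1", "ghost")))
  expect_match(got$log, "ghost", all = FALSE)
  expect_error(suppressMessages(altered_grouping(mat, "ghost")),
               "no signature gene")
})

test_that("Kaplan-Meier estimates, medians and log-rank behave as defined", {
  ## 5 subjects, events at 1..5: S = .8 .6 .4 .2 0, median = 3
  surv <- data.frame(time = 1:5, event = 1,
                     group = c("altered", "altered", "altered", "unaltered",
                               "unaltered"))
  ## single-group check of the product-limit curve via no-censoring identity
  fit_all <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  expect_equal(summary(fit_all)$surv, c(0.8, 0.6, 0.4, 0.2, 0))

  km <- km_analysis(surv)
  expect_equal(km$summary$median_months[km$summary$group == "altered"], 2)

  surv5 <- data.frame(time = rep(1:5, 2), event = 1,
                      group = rep(c("a", "b"), each = 5))
  km5 <- km_analysis(surv5)
  expect_equal(km5$summary$median_months, c(3, 3))
  ## identical groups: log-rank statistic 0, p = 1
  expect_equal(km5$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(km5$logrank_p, 1)

  ## KM with no censoring equals the empirical survival function
  set.seed(89)
  t_all <- sort(sample(1:100, 20))
  fit <- survival::survfit(survival::Surv(t_all, rep(1, 20)) ~ 1)
  emp <- vapply(summary(fit)$time, function(tt) mean(t_all > tt), 0)
  expect_equal(summary(fit)$surv, emp)

  ## censored-only group: median not reached
  survc <- data.frame(time = c(1:5, 10, 20, 30), event = c(rep(1, 5), 0, 0, 0),
                      group = c(rep("a", 5), rep("b", 3)))
  kmc <- km_analysis(survc)
  expect_true(is.na(kmc$summary$median_months[kmc$summary$group == "b"]))

  ## zero events overall: log-rank undefined
  got <- ps_log_collect(km_analysis(data.frame(time = 1:6, event = 0,
                                               group = rep(c("a", "b"), 3))))
  expect_true(is.na(got$value$logrank_p))
  expect_match(got$log, "zero events", all = FALSE)
})
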