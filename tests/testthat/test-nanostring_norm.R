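test_that("background threshold is mean + 2 sample SD of pooled negatives", {
  expect_equal(background_threshold(matrix(4, 2, 4)), 4)

  neg <- matrix(c(2, 4, 6, 8, 2, 4, 6, 8), nrow = 4)
  ## pooled {2,4,6,8} twice: mean 5, sum of squared deviations 40, df 7
  expect_equal(background_threshold(neg), 5 + 2 * sqrt(40 / 7))
  expect_error(background_threshold(matrix(3, 1, 1)), ">= 2")

  ## monotone in the negative-control SD at fixed mean
  spread <- function(s) background_threshold(5 + s * c(-1, -1, 1, 1))
  expect_true(spread(1) < spread(2) && spread(2) < spread(3))

  ## a gene above threshold in a single sample is retained
  thr <- background_threshold(neg)
  mat <- expression_matrix(rbind(lowgene = c(0, 0, thr + 1),
                                 deadgene = c(0, 1, 2)),
                           sample_ids = c("s1", "s2", "s3"))
  kept <- suppressMessages(background_filter(mat, thr))
  expect_identical(kept, "lowgene")
})

test_that("positive-control factors equalize geometric means", {
  pos_equal <- matrix(rep(c(100, 400), 3), nrow = 2)
  expect_equal(unname(positive_factor(pos_equal)), rep(1, 3))

  ## geomeans {100, 200, 400} -> factors (700/3) / each
  pos <- rbind(c(50, 100, 200), c(200, 400, 800))
  expect_equal(unname(positive_factor(pos)), c(7 / 3, 7 / 6, 7 / 12))

  ## doubling one sample's positives halves that sample's factor, up to the
  ## change in the grand mean
  f1 <- positive_factor(pos)
  pos2 <- pos
  pos2[, 1] <- pos2[, 1] * 2
  f2 <- positive_factor(pos2)
  expect_equal(f2[1] / f2[2], (f1[1] / 2) / f1[2])

  ## idempotence: after applying the factors, recomputed factors are all 1
  scaled <- sweep(pos, 2, positive_factor(pos), `*`)
  expect_equal(unname(positive_factor(scaled)), rep(1, 3))

  expect_error(positive_factor(rbind(c(1, 0), c(2, 3))), "> 0")
})

test_that("geNorm M matches the direct pairwise-SD formula", {
  set.seed(21)
  ## proportional genes have zero M
  base <- runif(6, 1, 10)
  two <- rbind(a = log2(base), b = log2(3 * base))
  st <- genorm_stability(two)
  expect_equal(unname(st$stability_m), c(0, 0))

  toy <- matrix(rnorm(12), 3, 4, dimnames = list(c("hk1", "hk2", "hk3"), NULL))
  st <- genorm_stability(toy)
  expect_equal(unname(st$stability_m), brute_genorm_m(toy))

  ## invariance: per-gene rescaling (additive in log space) and sample order
  shifted <- toy
  shifted[2, ] <- shifted[2, ] + 5
  expect_equal(genorm_stability(shifted)$stability_m, st$stability_m)
  perm <- toy[, c(3, 1, 4, 2)]
  expect_equal(genorm_stability(perm)$stability_m, st$stability_m)

  expect_error(genorm_stability(rbind(toy, bad = c(Inf, 1, 1, 1))), "finite")
})

test_that("geNorm selection drops the erratic candidate first", {
  set.seed(22)
  base <- rnorm(8)
  cands <- rbind(stable1 = base + rnorm(8, sd = 0.01),
                 stable2 = base + rnorm(8, sd = 0.01),
                 stable3 = base + rnorm(8, sd = 0.01),
                 erratic = rnorm(8, sd = 3))
  sel <- genorm_select(cands, target_count = 3)
  expect_false("erratic" %in% sel$selected_references)
  expect_identical(utils::tail(sel$ranked_genes, 1), "erratic")
  ## removal verified against exhaustive recomputation of M on the full set
  full_m <- brute_genorm_m(cands)
  expect_identical(rownames(cands)[which.max(full_m)], "erratic")

  ## pairwise-proportional candidates: tie-break is deterministic (last id)
  prop <- rbind(hkA = base, hkB = base + 1, hkC = base + 2)
  sel2 <- genorm_select(prop, 2)
  expect_identical(sel2$selected_references, c("hkA", "hkB"))

  sel3 <- genorm_select(cands, target_count = 4)
  expect_setequal(sel3$selected_references, rownames(cands))
  expect_error(genorm_select(cands, 5), "exceeds")
})

test_that("housekeeping normalization equalizes reference geomeans", {
  set.seed(23)
  mat <- expression_matrix(matrix(rpois(40, 100) + 1, 8,
                                  dimnames = list(c(sprintf("G%d", 1:6), "hk1", "hk2"),
                                                  sprintf("s%d", 1:5))))
  norm <- housekeeping_normalize(mat, c("hk1", "hk2"))
  gm <- apply(norm[c("hk1", "hk2"), ], 2, function(x) exp(mean(log(x))))
  expect_lt(diff(range(gm)) / mean(gm), 1e-9)

  ## already-normalized input is unchanged
  again <- housekeeping_normalize(norm, c("hk1", "hk2"))
  expect_equal(unclass(again)[, ], unclass(norm)[, ])

  expect_error(housekeeping_normalize(mat, "absent"), "absent")
})

test_that("references tracking library size remove the library-size effect", {
  set.seed(24)
  n_genes <- 120; n_samples <- 10
  lib <- rlnorm(n_samples, sdlog = 0.6)
  mu <- outer(rlnorm(n_genes, log(100), 1), lib)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 5), n_genes) + 1
  rownames(counts) <- sprintf("G%03d", 1:n_genes)
  colnames(counts) <- sprintf("s%02d", 1:n_samples)
  refs <- rownames(counts)[1:6]
  pre_gm <- apply(counts[refs, ], 2, function(x) exp(mean(log(x))))
  expect_gt(cor(pre_gm, colSums(counts)), 0.8)   # confound present by design
  norm <- housekeeping_normalize(expression_matrix(counts), refs)
  post_gm <- apply(norm[refs, ], 2, function(x) exp(mean(log(x))))
  expect_lt(stats::sd(post_gm) / mean(post_gm), 1e-9)
})

test_that("the full normalization wrapper runs on a simulated panel", {
  sim <- simulate_paired_cohort(n_patients = 4, n_genes = 80, de_frac = 0,
                                seed = 42)
  out <- suppressMessages(normalize_nanostring(sim$counts, sim$controls))
  expect_identical(scale_tag(out$normalized), "normalized")
  expect_true(all(out$genorm$selected_references %in%
                    sim$controls$housekeeping_genes))
  expect_gt(out$threshold, 0)
})
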