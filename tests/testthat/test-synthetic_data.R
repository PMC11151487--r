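test_that("generators are pure functions of their seed", {
  a <- simulate_paired_cohort(n_patients = 4, n_genes = 60, seed = 91)
  b <- simulate_paired_cohort(n_patients = 4, n_genes = 60, seed = 91)
  expect_identical(a, b)
  c_ <- simulate_paired_cohort(n_patients = 4, n_genes = 60, seed = 92)
  expect_false(identical(a$counts, c_$counts))

  s1 <- simulate_survival(setNames(rep(c("altered", "unaltered"), 10),
                                   sprintf("s%d", 1:20)), seed = 93)
  s2 <- simulate_survival(setNames(rep(c("altered", "unaltered"), 10),
                                   sprintf("s%d", 1:20)), seed = 93)
  expect_identical(s1, s2)
})

test_that("generated cohorts satisfy the container invariants and round-trip", {
  sim <- simulate_paired_cohort(n_patients = 5, n_genes = 100, seed = 94)
  expect_identical(scale_tag(sim$counts), "raw_counts")
  expect_true(all(sim$counts >= 0))
  expect_equal(ncol(sim$counts), 10)
  expect_silent(validate_metadata(sim$meta))
  expect_equal(dim(sim$controls$positive_controls), c(6, 10))
  expect_equal(dim(sim$controls$negative_controls), c(8, 10))
  expect_gte(length(sim$controls$housekeeping_genes), 10)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$counts, path)
  expect_equal(unclass(read_expression(path))[, ], unclass(sim$counts)[, ])
})

test_that("a null generator yields an FDR-consistent near-empty DEG list", {
  sim <- simulate_paired_cohort(n_patients = 7, n_genes = 500, de_frac = 0,
                                seed = 95)
  pairing <- study_pairing(sim$meta)
  hk <- sim$controls$housekeeping_genes
  tab <- suppressMessages(deg_table(sim$counts[setdiff(rownames(sim$counts), hk), ],
                                    pairing))
  expect_lte(sum(tab$direction != "none"), 5)
})

test_that("planted fold changes are recovered with high power", {
  ## median recovery over replicates at a 2-fold planted effect
  recov <- vapply(1:10, function(r) {
    sim <- simulate_paired_cohort(n_patients = 7, n_genes = 300, de_frac = 0.1,
                                  effect_log2fc = 2, down_frac = 0, seed = 200 + r)
    norm <- suppressMessages(normalize_nanostring(sim$counts, sim$controls))
    hk <- sim$controls$housekeeping_genes
    endo <- setdiff(rownames(norm$normalized), hk)
    tab <- suppressMessages(deg_table(norm$normalized[endo, ],
                                      study_pairing(sim$meta)))
    hits <- tab$gene[tab$direction != "none"]
    mean(sim$truth$de_genes %in% hits)
  }, 0)
  expect_gte(median(recov), 0.8)
})

test_that("the augmentation cohort reproduces the histology exclusion counts", {
  genes <- sprintf("G%04d", 1:50)
  aug <- simulate_augmentation_cohort(genes, seed = 96)
  expect_equal(ncol(aug$counts), 373)
  kept <- suppressMessages(
    filter_cohort(aug$meta, names(aug$truth$exclusions)))
  expect_length(kept, 360)
  aug0 <- simulate_augmentation_cohort(genes, n_total = 50,
                                       exclusions = integer(0), seed = 96)
  expect_identical(filter_cohort(aug0$meta, character(0)), aug0$meta$sample_id)
  expect_error(simulate_augmentation_cohort(genes, n_total = 10,
                                            exclusions = c(x = 11)), "exceed")

  ## marginal distribution shift versus a paired cohort is present by design
  sim <- simulate_paired_cohort(n_patients = 5, n_genes = 50, seed = 97)
  aug2 <- simulate_augmentation_cohort(
    rownames(sim$counts)[1:50], reference_mu = NULL, seed = 97)
  shared <- intersect(rownames(sim$counts), rownames(aug2$counts))
  m_study <- rowMeans(sim$counts[shared, ])
  m_aug <- rowMeans(aug2$counts[shared, ])
  expect_gt(median(abs(log2((m_aug + 1) / (m_study + 1)))), 0.3)
})

test_that("signal planting shifts only the designated cells", {
  set.seed(98)
  mat <- matrix(rnorm(40 * 10), 40, dimnames = list(sprintf("g%02d", 1:40),
                                                    sprintf("s%02d", 1:10)))
  rec <- colnames(mat)[9:10]
  out0 <- plant_term_signal(mat, sprintf("g%02d", 1:5), rec, shift_sd = 0)
  expect_identical(out0$matrix, mat)

  out <- plant_term_signal(mat, sprintf("g%02d", 1:5), rec, shift_sd = 2)
  changed <- out$matrix != mat
  expect_true(all(changed[1:5, 9:10]))
  expect_false(any(changed[6:40, ]))
  expect_false(any(changed[, 1:8]))
  expect_error(plant_term_signal(mat, "nope", rec, 1), "absent")
})

test_that("exponential survival respects the hazard ratio and censoring", {
  groups <- setNames(rep(c("altered", "unaltered"), each = 200),
                     sprintf("s%03d", 1:400))
  ratios <- vapply(1:40, function(r) {
    sv <- simulate_survival(groups, hr = 3, median_unaltered_months = 30,
                            censor_frac = 0, seed = 300 + r)
    median(sv$time[sv$group == "altered"]) /
      median(sv$time[sv$group == "unaltered"])
  }, 0)
  expect_lt(abs(median(ratios) - 1 / 3), 0.15 / 3)

  svc <- simulate_survival(groups, censor_frac = 1, seed = 99)
  expect_equal(sum(svc$event), 0)
  km <- suppressMessages(km_analysis(svc))
  expect_true(all(is.na(km$summary$median_months)))
})
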