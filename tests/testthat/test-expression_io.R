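test_that("expression TSV round-trips and rejects malformed input", {
  set.seed(11)
  mat <- expression_matrix(matrix(round(runif(15, 0, 1000), 3), 5,
                                  dimnames = list(sprintf("G%d", 1:5),
                                                  sprintf("S%d", 1:3))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(mat, path)
  back <- read_expression(path)
  expect_equal(unclass(back)[, ], unclass(mat)[, ])
  expect_identical(rownames(back), rownames(mat))
  expect_identical(scale_tag(back), "raw_counts")

  ## duplicated gene row errors naming the offender
  writeLines(c("gene\tS1", "IL6\t5", "IL6\t7"), path)
  expect_error(read_expression(path), "IL6")

  ## non-numeric cell errors with location
  writeLines(c("gene\tS1\tS2", "TNF\t3\tx"), path)
  expect_error(read_expression(path), "TNF")

  expect_error(expression_matrix(matrix(-1, 1, 1, dimnames = list("a", "s")),
                                 scale_tag = "raw_counts"), "non-negative")
})

test_that("GMT parsing deduplicates genes and round-trips collections", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("WP4172\tPI3K-Akt\tAKT1\tPIK3CA", path)
  coll <- read_gmt(path, "pathway")
  expect_identical(coll$genes[[1]], c("AKT1", "PIK3CA"))

  writeLines("T1\tname\tIL6\tIL6\tTNF", path)
  expect_length(read_gmt(path, "pathway")$genes[[1]], 2)

  writeLines("T1\tonlyname", path)
  expect_error(read_gmt(path, "pathway"), "line 1")

  ## 50 random sets round-trip
  set.seed(7)
  genes <- sprintf("G%03d", 1:200)
  coll <- data.frame(term_id = sprintf("T%02d", 1:50),
                     term_name = sprintf("set %d", 1:50),
                     category = "go_bp",
                     genes = I(lapply(1:50, function(i) sample(genes, sample(3:20, 1)))))
  write_gmt(coll, path)
  back <- read_gmt(path, "go_bp")
  expect_identical(back$term_id, coll$term_id)
  expect_identical(lapply(back$genes, sort), lapply(coll$genes, sort))
})

test_that("metadata and edge lists round-trip; paired design is enforced", {
  meta <- data.frame(sample_id = c("a", "b", "c"), patient_id = c("p1", "p1", "p2"),
                     tissue_class = c("primary", "recurrent", "primary"),
                     cohort = "study", histology_label = "hcc")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, path)
  expect_equal(read_metadata(path), meta)

  orphan <- meta
  orphan$patient_id[2] <- "p9"   # recurrent without a primary mate
  expect_error(validate_metadata(orphan), "p9")

  edges <- data.frame(gene_a = c("IL6", "TNF"), gene_b = c("TNF", "CD86"),
                      score = c(0.9, 0.41))
  write_edge_list(edges, path)
  expect_equal(read_edge_list(path), edges)
})

test_that("histology filter reproduces the 373 -> 360 exclusion and shrinks monotonically", {
  set.seed(3)
  labels <- c(rep("hcc", 360), rep("combined_hcc_chol", 8),
              rep("fibrolamellar", 3), rep("recurrent_tissue", 2))
  labels <- sample(labels)
  meta <- data.frame(sample_id = sprintf("S%03d", 1:373),
                     patient_id = sprintf("S%03d", 1:373),
                     tissue_class = "primary", cohort = "augmentation",
                     histology_label = labels)
  excl <- c("combined_hcc_chol", "fibrolamellar", "recurrent_tissue")
  kept <- suppressMessages(filter_cohort(meta, excl))
  expect_length(kept, 360)
  expect_identical(kept, meta$sample_id[meta$histology_label == "hcc"])

  expect_identical(filter_cohort(meta, character(0)), meta$sample_id)
  expect_length(suppressMessages(filter_cohort(meta, unique(labels))), 0)
  expect_error(filter_cohort(meta[0, ], excl), "empty")

  ## monotone shrinkage: filtering on a union is a subset of either filter
  for (i in 1:5) {
    l1 <- sample(unique(labels), 2)
    l2 <- sample(unique(labels), 1)
    expect_true(all(suppressMessages(filter_cohort(meta, union(l1, l2))) %in%
                      suppressMessages(filter_cohort(meta, l1))))
  }
})

test_that("cohort merge intersects genes, is symmetric, and rejects collisions", {
  set.seed(5)
  g_all <- sprintf("G%04d", 1:900)
  study <- expression_matrix(matrix(rpois(760 * 4, 50), 760,
                                    dimnames = list(g_all[1:760], sprintf("st%d", 1:4))))
  aug <- expression_matrix(matrix(rpois(840 * 3, 50), 840,
                                  dimnames = list(g_all[61:900], sprintf("au%d", 1:3))))
  merged <- suppressMessages(merge_cohorts(study, aug))
  expect_equal(nrow(merged), 700)           # overlap of the two id ranges
  expect_equal(ncol(merged), 7)
  expect_setequal(rownames(merged),
                  rownames(suppressMessages(merge_cohorts(aug, study))))

  renamed <- study
  colnames(renamed) <- paste0("x_", colnames(study))
  self_merge <- suppressMessages(merge_cohorts(study, renamed))
  expect_setequal(rownames(self_merge), rownames(study))

  expect_error(merge_cohorts(study, study), "collision")
  disjoint <- expression_matrix(matrix(1, 2, 1, dimnames = list(c("zz1", "zz2"), "q")))
  expect_error(suppressMessages(merge_cohorts(study, disjoint)), "intersection")
})
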