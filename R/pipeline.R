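## Orchestration: one validated config object holding every scalar
## threshold of the analysis, a staged runner operating on a run directory,
## and a manifest recording config, seeds and content digests of every
## output file so deterministic stages can be verified byte-for-byte.

#' Default pipeline configuration
#'
#' All numeric thresholds of the analysis in one place. Statistical cutoffs
#' carry the study's values (DEG filter q <= 0.05 with |FC| >= 1.5;
#' enrichment report tier adjusted p < 0.001; classifier curation tier
#' adjusted p < 0.05 with >= 5 DE genes per pathway and >= 10 per GO term;
#' 10 bootstraps; high-performer accuracy strictly > 0.80; importance
#' threshold 0.01 in >= 50% of high performers; altered-group z > 2).
#' Generator sizes default to the study design (7 paired patients on a
#' 760-gene panel; 373 augmentation samples of which 13 carry excluded
#' histologies).
#'
#' @return named list of class `pipeline_config`
#' @export
default_config <- function() {
  structure(list(
    ## cohort / generator
    n_patients = 7, n_genes = 760, n_housekeeping = 12,
    de_frac = 0.1, effect_log2fc = 1.5, dispersion = 0.1,
    n_augmentation = 373,
    exclusions = c(combined_hcc_chol = 8, fibrolamellar = 3,
                   recurrent_tissue = 2),
    n_terms = 40, term_size_min = 10, term_size_max = 60,
    n_signal_terms = 6, signal_genes_per_term = 20,
    ## normalization
    n_references = 5, count_offset = 1,
    ## differential expression
    q_method = "bh", q_cut = 0.05, fc_cut = 1.5,
    ## enrichment
    enrich_report_cut = 0.001, enrich_top_n = 10,
    dl_curation_cut = 0.05, min_genes_pathway = 5, min_genes_go = 10,
    min_links = 5, bridge_top_per_category = 5,
    ## network
    hub_k = 10, clique_node_guard = 5000,
    ## deconvolution
    n_cell_types = 22,
    ## classifier
    n_boot = 10, test_fraction = 0.2, epochs = 100, learning_rate = 0.05,
    batch_size = 32, balance_ratio = 1,
    acc_cut = 0.80, shap_cut = 0.01, consensus_frac = 0.50,
    shap_n_perm = 8, shap_max_background = 8, shap_max_instances = 16,
    signature_size = 20,
    ## survival
    altered_z_cut = 2, survival_hr = 29.66 / 15.70,
    median_unaltered_months = 29.66,
    censor_frac = 0.2,
    seed = 1
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#' @param config list of config values
#' @return the config, invisibly, or an error listing offending keys
#' @export
validate_config <- function(config) {
  checks <- list(
    q_cut = config$q_cut > 0 && config$q_cut <= 1,
    fc_cut = config$fc_cut > 1,
    enrich_report_cut = config$enrich_report_cut > 0 && config$enrich_report_cut <= 1,
    dl_curation_cut = config$dl_curation_cut > 0 && config$dl_curation_cut <= 1,
    min_genes_pathway = config$min_genes_pathway >= 1,
    min_genes_go = config$min_genes_go >= 1,
    n_boot = config$n_boot >= 1,
    acc_cut = config$acc_cut >= 0 && config$acc_cut < 1,
    shap_cut = config$shap_cut >= 0,
    consensus_frac = config$consensus_frac > 0 && config$consensus_frac <= 1,
    altered_z_cut = config$altered_z_cut > 0,
    test_fraction = config$test_fraction > 0 && config$test_fraction < 1,
    seed = is.numeric(config$seed) && config$seed >= 0 &&
      config$seed == round(config$seed)
  )
  bad <- names(checks)[!vapply(checks, isTRUE, TRUE)]
  if (length(bad)) stop("config value(s) out of range: ", paste(bad, collapse = ", "))
  invisible(config)
}

#' Read a config file (YAML or JSON), merged over the defaults
#' @param path config file; keys must be known config fields
#' @return validated `pipeline_config`
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
  cfg
}

## per-term training seed, kept well inside the 32-bit integer range
stage_seed <- function(seed, term_index) {
  (seed %% 1000000) * 1000 + 100 * term_index
}

manifest_path <- function(outdir) file.path(outdir, "manifest.json")

read_manifest <- function(outdir) {
  p <- manifest_path(outdir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list(stages = list(), files = list())
}

record_stage <- function(outdir, name, config, files) {
  man <- read_manifest(outdir)
  digests <- as.list(tools::md5sum(files))
  names(digests) <- basename(files)
  man$tool_version <- as.character(utils::packageVersion("pathsig"))
  man$config <- config[setdiff(names(config), "exclusions")]
  man$config$exclusions <- as.list(config$exclusions)
  man$stages[[name]] <- list(completed = TRUE, seed = config$seed,
                             outputs = names(digests))
  man$files <- utils::modifyList(man$files %||% list(), digests)
  jsonlite::write_json(man, manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(man)
}

stage_input <- function(outdir, file, stage, needed_by) {
  p <- file.path(outdir, file)
  if (!file.exists(p)) {
    stop(sprintf("stage '%s' needs '%s' (produced by stage '%s'); run it first",
                 needed_by, p, stage))
  }
  p
}

#' Run one pipeline stage (or all) on a run directory
#'
#' Stages: simulate, normalize, de, enrich, hubs, deconv, train, consensus,
#' survival, or all (the full sequence). Each stage reads its predecessors'
#' outputs from `outdir`, writes its own TSV/JSON outputs there, and records
#' them in `manifest.json` with content digests. Missing upstream outputs
#' raise an error naming the expected file.
#'
#' @param name stage name
#' @param config a `pipeline_config` (see [default_config()])
#' @param outdir run directory (created if absent)
#' @return the updated manifest, invisibly
#' @export
run_stage <- function(name = c("simulate", "normalize", "de", "enrich", "hubs",
                               "deconv", "train", "consensus", "survival", "all"),
                      config = default_config(), outdir) {
  name <- match.arg(name)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") {
    for (st in c("simulate", "normalize", "de", "enrich", "hubs", "deconv",
                 "train", "consensus", "survival")) {
      run_stage(st, config, outdir)
    }
    return(invisible(read_manifest(outdir)))
  }
  ps_log(sprintf("running stage '%s' in %s", name, outdir), stage = "pipeline")
  fn <- switch(name,
               simulate = stage_simulate, normalize = stage_normalize,
               de = stage_de, enrich = stage_enrich, hubs = stage_hubs,
               deconv = stage_deconv, train = stage_train,
               consensus = stage_consensus, survival = stage_survival)
  files <- fn(config, outdir)
  invisible(record_stage(outdir, name, config, files))
}

## ---- stages ----------------------------------------------------------------

stage_simulate <- function(config, outdir) {
  seed <- config$seed
  cohort <- simulate_paired_cohort(config$n_patients, config$n_genes,
                                   config$de_frac, config$effect_log2fc,
                                   config$dispersion, config$n_housekeeping,
                                   seed = seed)
  aug <- simulate_augmentation_cohort(
    gene_ids = setdiff(rownames(cohort$counts),
                       cohort$controls$housekeeping_genes),
    n_total = config$n_augmentation, exclusions = config$exclusions,
    seed = seed + 1)
  ## signal terms are built around the planted DE genes so the enrichment
  ## curation tier has something real to find; drawing from a concentrated
  ## pool (not the whole DE list) gives the terms the overlap structure the
  ## bridge-gene analysis looks at
  signal_terms <- with_seed(seed + 5, {
    ids <- sprintf("TERM%02d", seq_len(config$n_signal_terms))
    pool <- utils::head(cohort$truth$de_genes,
                        max(2 * config$signal_genes_per_term, 10))
    stats::setNames(lapply(ids, function(i) {
      sample(pool, min(config$signal_genes_per_term, length(pool)))
    }), ids)
  })
  sets <- simulate_gene_sets(
    universe = setdiff(rownames(cohort$counts),
                       cohort$controls$housekeeping_genes),
    n_terms = config$n_terms,
    size_range = c(config$term_size_min, config$term_size_max),
    signal_terms = signal_terms,
    seed = seed + 2)
  sig <- simulate_signature_matrix(n_cell_types = config$n_cell_types,
                                   seed = seed + 3)
  ## immune mixtures for the study samples, with a planted composition
  ## difference (the first two cell types trade mass in recurrent tumors)
  fracs <- with_seed(seed + 4, {
    raw <- matrix(stats::rgamma(2 * config$n_patients * ncol(sig), shape = 2),
                  2 * config$n_patients, ncol(sig))
    f <- raw / rowSums(raw)
    rec_rows <- which(cohort$meta$tissue_class == "recurrent")
    f[rec_rows, 1] <- f[rec_rows, 1] + 0.12
    f[rec_rows, 2] <- pmax(f[rec_rows, 2] - 0.08, 0.005)
    f / rowSums(f)
  })
  colnames(fracs) <- colnames(sig)
  rownames(fracs) <- cohort$meta$sample_id
  mix <- simulate_mixtures(sig, fractions = fracs, noise_sd = 0.05,
                           seed = seed + 4)
  colnames(mix$expr) <- colnames(cohort$counts)
  rownames(mix$fractions) <- colnames(cohort$counts)

  f <- c(counts = "counts.tsv", aug_counts = "augmentation_counts.tsv",
         meta = "metadata.tsv", aug_meta = "augmentation_metadata.tsv",
         pathways = "pathways.gmt", go = "go_bp.gmt",
         signature = "immune_signature.tsv", immune = "immune_mixture.tsv",
         truth = "truth.json", positives = "positive_controls.tsv",
         negatives = "negative_controls.tsv", housekeeping = "housekeeping.txt")
  paths <- file.path(outdir, f)
  names(paths) <- names(f)
  write_expression(cohort$counts, paths["counts"])
  write_expression(aug$counts, paths["aug_counts"])
  write_metadata(cohort$meta, paths["meta"])
  write_metadata(aug$meta, paths["aug_meta"])
  write_gmt(sets[sets$category == "pathway", ], paths["pathways"])
  write_gmt(sets[sets$category == "go_bp", ], paths["go"])
  utils::write.table(data.frame(gene_id = rownames(sig), sig, check.names = FALSE),
                     paths["signature"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(mix$expr), mix$expr,
                                check.names = FALSE),
                     paths["immune"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(control_id = rownames(cohort$controls$positive_controls),
                                cohort$controls$positive_controls, check.names = FALSE),
                     paths["positives"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(control_id = rownames(cohort$controls$negative_controls),
                                cohort$controls$negative_controls, check.names = FALSE),
                     paths["negatives"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$controls$housekeeping_genes, paths["housekeeping"])
  jsonlite::write_json(list(de_genes = cohort$truth$de_genes,
                            effects_log2 = as.list(cohort$truth$effects_log2),
                            immune_fractions = as.data.frame(mix$fractions),
                            params = cohort$truth$params),
                       paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}

load_controls <- function(outdir, needed_by) {
  pos <- utils::read.delim(stage_input(outdir, "positive_controls.tsv",
                                       "simulate", needed_by), row.names = 1)
  neg <- utils::read.delim(stage_input(outdir, "negative_controls.tsv",
                                       "simulate", needed_by), row.names = 1)
  hk <- readLines(stage_input(outdir, "housekeeping.txt", "simulate", needed_by))
  control_set(as.matrix(pos), as.matrix(neg), hk)
}

stage_normalize <- function(config, outdir) {
  counts <- read_expression(stage_input(outdir, "counts.tsv", "simulate",
                                        "normalize"))
  controls <- load_controls(outdir, "normalize")
  norm <- normalize_nanostring(counts, controls,
                               n_references = config$n_references,
                               offset = config$count_offset)
  out <- file.path(outdir, c("normalized.tsv", "normalization.json"))
  write_expression(norm$normalized, out[1])
  jsonlite::write_json(list(threshold = norm$threshold,
                            retained_genes = norm$retained_genes,
                            positive_factors = as.list(norm$positive_factors),
                            genorm_references = norm$genorm$selected_references,
                            genorm_m = as.list(norm$genorm$stability_m)),
                       out[2], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}

stage_de <- function(config, outdir) {
  norm <- read_expression(stage_input(outdir, "normalized.tsv", "normalize", "de"),
                          scale_tag = "normalized")
  meta <- read_metadata(stage_input(outdir, "metadata.tsv", "simulate", "de"))
  hk <- readLines(stage_input(outdir, "housekeeping.txt", "simulate", "de"))
  pairing <- study_pairing(meta)
  tab <- deg_table(norm[setdiff(rownames(norm), hk), , drop = FALSE], pairing,
                   q_method = config$q_method, q_cut = config$q_cut,
                   fc_cut = config$fc_cut, offset = config$count_offset)
  out <- file.path(outdir, "deg_table.tsv")
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

load_deg <- function(outdir, needed_by) {
  utils::read.delim(stage_input(outdir, "deg_table.tsv", "de", needed_by))
}

stage_enrich <- function(config, outdir) {
  tab <- load_deg(outdir, "enrich")
  degs <- tab$gene[tab$direction != "none"]
  universe <- tab$gene
  coll <- rbind(read_gmt(stage_input(outdir, "pathways.gmt", "simulate", "enrich"),
                         "pathway"),
                read_gmt(stage_input(outdir, "go_bp.gmt", "simulate", "enrich"),
                         "go_bp"))
  enr <- hypergeom_enrich(degs, universe, coll)
  rep_tab <- report_terms(enr, config$enrich_report_cut, config$enrich_top_n)
  cur <- curate_for_dl(enr, config$dl_curation_cut,
                       config$min_genes_pathway, config$min_genes_go)
  br <- bridge_genes(enr, config$min_links, config$bridge_top_per_category)
  out <- file.path(outdir, c("enrichment.tsv", "enrichment_report.tsv",
                             "curated_terms.gmt", "bridge_genes.tsv"))
  write_enrichment(enr, out[1])
  write_enrichment(rep_tab, out[2])
  if (nrow(cur)) {
    write_gmt(data.frame(term_id = cur$term_id,
                         term_name = paste(cur$category, cur$term_name),
                         genes = I(cur$genes)), out[3])
  } else writeLines(character(0), out[3])
  utils::write.table(br$bridge_genes, out[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ## carry the curated categories for the train stage
  saveRDS_free <- file.path(outdir, "curated_categories.tsv")
  utils::write.table(data.frame(term_id = cur$term_id, category = cur$category),
                     saveRDS_free, sep = "\t", quote = FALSE, row.names = FALSE)
  c(out, saveRDS_free)
}

stage_hubs <- function(config, outdir) {
  tab <- load_deg(outdir, "hubs")
  degs <- tab$gene[tab$direction != "none"]
  if (length(degs) < 3) stop("too few DEGs to build a PPI network")
  ## synthetic interactome over the DEGs: a planted dense core plus sparse
  ## background, seeded from the run seed
  edges <- with_seed(config$seed + 10, {
    core <- utils::head(degs, min(10, length(degs)))
    core_e <- t(utils::combn(core, 2))
    n_bg <- min(12 * length(degs), choose(length(degs), 2))
    bg_a <- sample(degs, n_bg, replace = TRUE)
    bg_b <- sample(degs, n_bg, replace = TRUE)
    keep <- bg_a != bg_b
    e <- unique(rbind(core_e,
                      t(apply(cbind(bg_a[keep], bg_b[keep]), 1, sort))))
    data.frame(gene_a = e[, 1], gene_b = e[, 2],
               score = round(stats::runif(nrow(e), 0.4, 1), 3),
               stringsAsFactors = FALSE)
  })
  g <- ppi_graph(edges)
  hubs <- top_k_hubs(mcc_scores(g), k = min(config$hub_k, igraph::vcount(g)))
  out <- file.path(outdir, c("ppi_edges.tsv", "hub_genes.tsv"))
  write_edge_list(edges, out[1])
  utils::write.table(hubs, out[2], sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

stage_deconv <- function(config, outdir) {
  sig <- as.matrix(utils::read.delim(
    stage_input(outdir, "immune_signature.tsv", "simulate", "deconv"),
    row.names = 1, check.names = FALSE))
  mixture <- as.matrix(utils::read.delim(
    stage_input(outdir, "immune_mixture.tsv", "simulate", "deconv"),
    row.names = 1, check.names = FALSE))
  meta <- read_metadata(stage_input(outdir, "metadata.tsv", "simulate", "deconv"))
  fr <- deconvolve(mixture, sig)
  cmp <- compare_fractions(fr, study_pairing(meta))
  out <- file.path(outdir, c("immune_fractions.tsv", "immune_comparison.tsv"))
  utils::write.table(fr, out[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cmp, out[2], sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

## Shared train-stage setup: merged cohort, curated terms, sample classes.
train_inputs <- function(config, outdir, needed_by) {
  norm <- read_expression(stage_input(outdir, "normalized.tsv", "normalize",
                                      needed_by), scale_tag = "normalized")
  hk <- readLines(stage_input(outdir, "housekeeping.txt", "simulate", needed_by))
  meta <- read_metadata(stage_input(outdir, "metadata.tsv", "simulate", needed_by))
  aug <- read_expression(stage_input(outdir, "augmentation_counts.tsv",
                                     "simulate", needed_by))
  aug_meta <- read_metadata(stage_input(outdir, "augmentation_metadata.tsv",
                                        "simulate", needed_by))
  curated_lines <- readLines(stage_input(outdir, "curated_terms.gmt", "enrich",
                                         needed_by))
  curated_lines <- curated_lines[nzchar(trimws(curated_lines))]
  cats <- utils::read.delim(stage_input(outdir, "curated_categories.tsv",
                                        "enrich", needed_by))
  if (!length(curated_lines)) stop("no curated terms; nothing to train")
  terms <- lapply(curated_lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    list(term_id = fields[1], genes = fields[-(1:2)])
  })
  names(terms) <- vapply(terms, `[[`, "", "term_id")
  keep_aug <- filter_cohort(aug_meta, names(config$exclusions))
  merged <- merge_cohorts(
    expression_matrix(log2(norm[setdiff(rownames(norm), hk), , drop = FALSE] +
                             config$count_offset), scale_tag = "log2"),
    expression_matrix(log2(aug[, keep_aug, drop = FALSE] + config$count_offset),
                      scale_tag = "log2"))
  primary_ids <- c(meta$sample_id[meta$tissue_class == "primary"], keep_aug)
  recurrent_ids <- meta$sample_id[meta$tissue_class == "recurrent"]
  list(merged = merged, terms = terms,
       categories = stats::setNames(cats$category, cats$term_id),
       primary_ids = intersect(primary_ids, colnames(merged)),
       recurrent_ids = intersect(recurrent_ids, colnames(merged)))
}

stage_train <- function(config, outdir) {
  inp <- train_inputs(config, outdir, "train")
  rows <- list(); runs <- list()
  for (term in names(inp$terms)) {
    ti <- match(term, names(inp$terms))
    genes <- intersect(inp$terms[[term]]$genes, rownames(inp$merged))
    if (length(genes) < 2) {
      ps_log(sprintf("train: term %s has < 2 genes in merged matrix; skipped", term),
             stage = "pipeline")
      next
    }
    spec <- model_spec(length(genes), epochs = config$epochs,
                       learning_rate = config$learning_rate,
                       batch_size = config$batch_size,
                       balance_ratio = config$balance_ratio)
    run <- run_bootstraps(inp$merged, genes, inp$primary_ids, inp$recurrent_ids,
                          n_boot = config$n_boot,
                          base_seed = stage_seed(config$seed, ti),
                          test_fraction = config$test_fraction, spec = spec)
    runs[[term]] <- run
    met <- do.call(rbind, lapply(seq_along(run$results), function(b) {
      data.frame(term_id = term, bootstrap = b,
                 t(run$results[[b]]$metrics), stringsAsFactors = FALSE)
    }))
    rows[[term]] <- met
  }
  if (!length(rows)) stop("no trainable term")
  metrics <- do.call(rbind, rows)
  out <- file.path(outdir, c("model_metrics.tsv", "model_metrics_summary.tsv"))
  utils::write.table(metrics, out[1], sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- metric_summary(do.call(c, lapply(runs, `[[`, "results")))
  utils::write.table(data.frame(metric = names(summ), median = unname(summ)),
                     out[2], sep = "\t", quote = FALSE, row.names = FALSE)
  ## keep runs in memory for a same-session consensus stage
  .pathsig_env$term_runs <- runs
  out
}

stage_consensus <- function(config, outdir) {
  runs <- .pathsig_env$term_runs
  if (is.null(runs)) {
    inp <- train_inputs(config, outdir, "consensus")
    stage_input(outdir, "model_metrics.tsv", "train", "consensus")
    ## retrain deterministically (same seeds) to recover the model objects
    runs <- list()
    for (term in names(inp$terms)) {
      ti <- match(term, names(inp$terms))
      genes <- intersect(inp$terms[[term]]$genes, rownames(inp$merged))
      if (length(genes) < 2) next
      spec <- model_spec(length(genes), epochs = config$epochs,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         balance_ratio = config$balance_ratio)
      runs[[term]] <- run_bootstraps(inp$merged, genes, inp$primary_ids,
                                     inp$recurrent_ids, n_boot = config$n_boot,
                                     base_seed = stage_seed(config$seed, ti),
                                     test_fraction = config$test_fraction,
                                     spec = spec)
    }
  }
  cats_file <- stage_input(outdir, "curated_categories.tsv", "enrich", "consensus")
  cats_df <- utils::read.delim(cats_file)
  categories <- stats::setNames(cats_df$category, cats_df$term_id)
  cons <- consensus_over_terms(runs, categories, acc_cut = config$acc_cut,
                               shap_cut = config$shap_cut,
                               frac = config$consensus_frac,
                               n_perm = config$shap_n_perm,
                               max_background = config$shap_max_background,
                               max_instances = config$shap_max_instances,
                               seed = config$seed)
  out <- file.path(outdir, c("consensus_selections.tsv", "discriminant_table.tsv",
                             "signature.txt"))
  utils::write.table(cons$selections, out[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(cons$selections)) {
    ds <- discriminant_scores(cons$selections, top_n = config$signature_size)
    utils::write.table(ds$table, out[2], sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(ds$signature, out[3])
  } else {
    ps_log("consensus: no gene passed the consensus rule", stage = "pipeline")
    utils::write.table(data.frame(), out[2], sep = "\t", row.names = FALSE)
    writeLines(character(0), out[3])
  }
  out
}

stage_survival <- function(config, outdir) {
  signature <- readLines(stage_input(outdir, "signature.txt", "consensus",
                                     "survival"))
  if (!length(signature)) stop("empty signature; cannot stratify")
  aug <- read_expression(stage_input(outdir, "augmentation_counts.tsv",
                                     "simulate", "survival"))
  aug_meta <- read_metadata(stage_input(outdir, "augmentation_metadata.tsv",
                                        "simulate", "survival"))
  keep <- filter_cohort(aug_meta, names(config$exclusions))
  lmat <- log2(aug[, keep, drop = FALSE] + config$count_offset)
  groups <- altered_grouping(lmat, signature, z_cut = config$altered_z_cut)
  if (length(unique(groups)) < 2) {
    stop("altered grouping produced a single group; no survival contrast")
  }
  surv <- simulate_survival(groups, hr = config$survival_hr,
                            median_unaltered_months = config$median_unaltered_months,
                            censor_frac = config$censor_frac,
                            seed = config$seed + 20)
  km <- km_analysis(surv)
  out <- file.path(outdir, c("survival_data.tsv", "survival_summary.tsv",
                             "survival_summary.json"))
  utils::write.table(surv, out[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(km$summary, out[2], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(summary = km$summary, logrank_chisq = km$logrank_chisq,
                            logrank_p = km$logrank_p,
                            n_altered = sum(groups == "altered")),
                       out[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}
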