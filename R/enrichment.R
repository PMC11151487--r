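## Over-representation analysis of the DEG list against pathway and GO
## biological-process collections: one-sided hypergeometric tail per term,
## BH adjustment within each category, the two-tier term selection (a
## stringent report tier and a looser curation tier feeding the per-pathway
## classifiers), and the bridge-gene analysis over the top terms.

#' Hypergeometric gene-set enrichment
#'
#' For each term, p = P(X >= k) with X ~ Hypergeometric(N = |universe|,
#' K = |term genes in universe|, n = |DE genes|), where k is the observed
#' overlap. Terms with no gene in the universe are skipped and logged.
#' Adjusted p-values are BH within each category.
#'
#' @param de_genes character vector of DE gene ids (must lie in `universe`)
#' @param universe background gene ids (e.g. panel genes surviving the
#'   background filter)
#' @param collection gene-set data.frame from [read_gmt()] (categories may
#'   be mixed; adjustment is per category)
#' @return data.frame term_id, term_name, category, k, K, N, n, p_value,
#'   adj_p, overlap_genes (list-column)
#' @export
hypergeom_enrich <- function(de_genes, universe, collection) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    stop("DE gene(s) outside the universe: ", paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    term_genes <- intersect(collection$genes[[i]], universe)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    overlap <- intersect(de_genes, term_genes)
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = collection$term_id[i],
               term_name = collection$term_name[i],
               category = collection$category[i],
               k = k, K = K, N = N, n = n, p_value = p,
               overlap_genes = I(list(overlap)),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped > 0) {
    ps_log(sprintf("hypergeom_enrich: %d term(s) with no gene in universe skipped",
                   skipped), stage = "enrichment")
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      N = integer(0), n = integer(0), p_value = numeric(0),
                      adj_p = numeric(0), overlap_genes = I(list())))
  }
  res <- do.call(rbind, rows)
  res$adj_p <- NA_real_
  for (cat in unique(res$category)) {
    idx <- res$category == cat
    res$adj_p[idx] <- stats::p.adjust(res$p_value[idx], method = "BH")
  }
  res
}

#' Report-tier term selection
#'
#' Terms with adjusted p strictly below `adj_cut`, ranked ascending by
#' adjusted p (ties by raw p, then term id), truncated to `top_n` within
#' each category.
#'
#' @param result enrichment data.frame from [hypergeom_enrich()]
#' @param adj_cut adjusted-p cutoff for reporting
#' @param top_n terms retained per category
#' @return filtered, ranked enrichment data.frame
#' @export
report_terms <- function(result, adj_cut = 0.001, top_n = 10) {
  keep <- result[result$adj_p < adj_cut, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  out <- lapply(unique(keep$category), function(cat) {
    sub <- keep[keep$category == cat, , drop = FALSE]
    sub <- sub[order(sub$adj_p, sub$p_value, sub$term_id), , drop = FALSE]
    utils::head(sub, top_n)
  })
  do.call(rbind, out)
}

#' Curation-tier term selection for the classifier stage
#'
#' Pathways need adjusted p < 0.05 and at least 5 DE genes; GO terms need
#' adjusted p < 0.05 and at least 10 DE genes. Each selected term carries
#' its DE-gene feature list.
#'
#' @param result enrichment data.frame
#' @param adj_cut adjusted-p cutoff (shared by both categories)
#' @param min_genes_pathway,min_genes_go per-category DE-gene floors
#' @return data.frame term_id, term_name, category, genes (list-column of DE
#'   genes in the term)
#' @export
curate_for_dl <- function(result, adj_cut = 0.05,
                          min_genes_pathway = 5, min_genes_go = 10) {
  floor_for <- ifelse(result$category == "pathway", min_genes_pathway, min_genes_go)
  keep <- result$adj_p < adj_cut & result$k >= floor_for
  sel <- result[keep, , drop = FALSE]
  sel <- sel[order(sel$category, sel$adj_p, sel$term_id), , drop = FALSE]
  data.frame(term_id = sel$term_id, term_name = sel$term_name,
             category = sel$category, genes = I(sel$overlap_genes),
             stringsAsFactors = FALSE)
}

#' Bridge genes over the top enriched terms
#'
#' Builds the gene-term bipartite graph over the top 5 pathways and top 5 GO
#' terms (by adjusted p; fewer if fewer are available, logged) and returns
#' the genes linked to at least `min_links` of those terms, sorted by link
#' count then gene id.
#'
#' @param result enrichment data.frame
#' @param min_links minimum number of term links for a bridge gene
#' @param top_per_category terms taken per category
#' @return list: `links` (data.frame gene, term_id), `bridge_genes`
#'   (data.frame gene, n_links), `terms_used`
#' @export
bridge_genes <- function(result, min_links = 5, top_per_category = 5) {
  tops <- lapply(unique(result$category), function(cat) {
    sub <- result[result$category == cat, , drop = FALSE]
    sub <- sub[order(sub$adj_p, sub$p_value, sub$term_id), , drop = FALSE]
    if (nrow(sub) < top_per_category) {
      ps_log(sprintf("bridge_genes: only %d %s term(s) available (wanted %d)",
                     nrow(sub), cat, top_per_category), stage = "enrichment")
    }
    utils::head(sub, top_per_category)
  })
  tops <- do.call(rbind, tops)
  links <- do.call(rbind, lapply(seq_len(nrow(tops)), function(i) {
    genes <- tops$overlap_genes[[i]]
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, term_id = tops$term_id[i], stringsAsFactors = FALSE)
  }))
  if (is.null(links)) {
    return(list(links = data.frame(gene = character(0), term_id = character(0)),
                bridge_genes = data.frame(gene = character(0), n_links = integer(0)),
                terms_used = tops$term_id))
  }
  counts <- table(links$gene)
  bg <- data.frame(gene = names(counts), n_links = as.integer(counts),
                   stringsAsFactors = FALSE)
  bg <- bg[bg$n_links >= min_links, , drop = FALSE]
  bg <- bg[order(-bg$n_links, bg$gene), , drop = FALSE]
  rownames(bg) <- NULL
  list(links = links, bridge_genes = bg, terms_used = tops$term_id)
}

#' Write an enrichment table as TSV
#' @param result enrichment data.frame
#' @param path output path
#' @export
write_enrichment <- function(result, path) {
  flat <- result
  flat$overlap_genes <- vapply(result$overlap_genes, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
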