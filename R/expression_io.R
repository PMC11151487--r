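## Reading/writing the pipeline's plain-text interchange formats and the
## cohort-level bookkeeping (metadata filters, cohort merging).
##
## Containers are deliberately plain: an expression matrix is a numeric
## matrix (genes x samples) with a `scale_tag` attribute; metadata is a
## data.frame; a gene-set collection is a data.frame of term rows with a
## list-column of gene ids. Everything round-trips losslessly through TSV.

#' Construct an expression matrix container
#'
#' @param values numeric matrix, genes in rows, samples in columns
#' @param gene_ids,sample_ids row/column identifiers (unique, non-empty)
#' @param scale_tag one of `"raw_counts"`, `"normalized"`, `"log2"`
#' @return the matrix with dimnames set and a `scale_tag` attribute
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale_tag = c("raw_counts", "normalized", "log2")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (scale_tag == "raw_counts" && any(values < 0)) {
    stop("raw counts must be non-negative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "scale_tag") <- scale_tag
  values
}

#' @rdname expression_matrix
#' @param x object to query
#' @export
scale_tag <- function(x) attr(x, "scale_tag") %||% "raw_counts"

#' Read an expression TSV (genes in rows, header = sample ids)
#'
#' @param path file path
#' @param scale_tag declared scale of the stored values
#' @return expression matrix (see [expression_matrix()])
#' @export
read_expression <- function(path, scale_tag = "raw_counts") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus >= 1 sample")
  gene_ids <- trimws(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene row %d ('%s'), sample column '%s'",
                 bad[1], gene_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  expression_matrix(num, gene_ids, colnames(vals), scale_tag)
}

#' Write an expression matrix as TSV
#' @param mat expression matrix
#' @param path output path
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' Columns: sample_id, patient_id, tissue_class (primary/recurrent),
#' cohort (study/augmentation), histology_label.
#' @param path file path
#' @return data.frame of metadata
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", colClasses = "character")
  validate_metadata(meta)
}

#' @rdname read_metadata
#' @param meta metadata data.frame
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "patient_id", "tissue_class", "cohort", "histology_label")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (!all(meta$tissue_class %in% c("primary", "recurrent"))) {
    stop("tissue_class must be 'primary' or 'recurrent'")
  }
  if (!all(meta$cohort %in% c("study", "augmentation"))) {
    stop("cohort must be 'study' or 'augmentation'")
  }
  ## paired design: every study recurrent sample needs a study primary mate
  st <- meta[meta$cohort == "study", , drop = FALSE]
  rec <- st[st$tissue_class == "recurrent", , drop = FALSE]
  prim_patients <- st$patient_id[st$tissue_class == "primary"]
  orphan <- setdiff(rec$patient_id, prim_patients)
  if (length(orphan)) {
    stop("recurrent sample(s) without a paired primary for patient(s): ",
         paste(orphan, collapse = ", "))
  }
  meta
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame
#' @param path output path
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, fields term_id, description, gene ids.
#' Genes are deduplicated within a set; the description is kept as term_name.
#' The `category` (pathway vs GO biological process) is assigned by the
#' caller, one collection file per category.
#'
#' @param path GMT file
#' @param category `"pathway"` or `"go_bp"`
#' @return data.frame: term_id, term_name, category, genes (list-column)
#' @export
read_gmt <- function(path, category = c("pathway", "go_bp")) {
  category <- match.arg(category)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  entries <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need term, name, >= 1 gene",
                   i, length(fields)))
    }
    genes <- unique(trimws(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d has no genes", i))
    list(term_id = trimws(fields[[1]]), term_name = fields[[2]], genes = genes)
  })
  ids <- vapply(entries, `[[`, "", "term_id")
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(
    term_id = ids,
    term_name = vapply(entries, `[[`, "", "term_name"),
    category = category,
    genes = I(lapply(entries, `[[`, "genes")),
    stringsAsFactors = FALSE
  )
}

#' Write a gene-set collection in GMT format
#' @param collection data.frame as returned by [read_gmt()]
#' @param path output path
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$term_id[i], collection$term_name[i],
            collection$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPI edge list TSV (gene_a, gene_b, optional score)
#' @param path file path
#' @return data.frame gene_a, gene_b, score
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("edge list needs columns gene_a, gene_b")
  }
  df$gene_a <- trimws(df$gene_a)
  df$gene_b <- trimws(df$gene_b)
  df$score <- if ("score" %in% names(df)) as.numeric(df$score) else NA_real_
  df[c("gene_a", "gene_b", "score")]
}

#' Write a PPI edge list TSV
#' @param edges data.frame gene_a, gene_b, score
#' @param path output path
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a cohort by histology label
#'
#' Drops samples whose histology label is in the exclusion set, e.g. mixed
#' hepatocellular/cholangiocarcinoma, fibrolamellar carcinoma and recurrent
#' tissue entries when assembling a primary-only augmentation cohort.
#'
#' @param meta metadata data.frame
#' @param exclude_labels character vector of labels to drop
#' @return retained sample ids, input order preserved
#' @export
filter_cohort <- function(meta, exclude_labels = character(0)) {
  if (is.null(meta) || nrow(meta) == 0) stop("empty metadata")
  keep <- !(meta$histology_label %in% exclude_labels)
  dropped <- sum(!keep)
  if (dropped > 0) {
    ps_log(sprintf("filter_cohort: dropped %d sample(s) with label(s) %s",
                   dropped, paste(unique(meta$histology_label[!keep]), collapse = ", ")),
           stage = "expression_io")
  }
  meta$sample_id[keep]
}

#' Merge two expression cohorts on their shared genes
#'
#' Restricts both matrices to the intersection of gene ids (exact string
#' match after whitespace trimming; unmatched genes are logged with counts,
#' never silently dropped) and binds samples. Sample id collisions error.
#'
#' @param study,augmentation expression matrices with a common scale
#' @return merged expression matrix on the shared genes
#' @export
merge_cohorts <- function(study, augmentation) {
  if (!identical(scale_tag(study), scale_tag(augmentation))) {
    stop("cannot merge matrices with different scale tags: ",
         scale_tag(study), " vs ", scale_tag(augmentation))
  }
  shared <- intersect(rownames(study), rownames(augmentation))
  if (!length(shared)) stop("empty gene intersection between cohorts")
  collide <- intersect(colnames(study), colnames(augmentation))
  if (length(collide)) {
    stop("sample id collision between cohorts: ", paste(collide, collapse = ", "))
  }
  lost_a <- nrow(study) - length(shared)
  lost_b <- nrow(augmentation) - length(shared)
  if (lost_a + lost_b > 0) {
    ps_log(sprintf("merge_cohorts: %d study-only and %d augmentation-only gene(s) dropped; %d shared retained",
                   lost_a, lost_b, length(shared)), stage = "expression_io")
  }
  expression_matrix(cbind(study[shared, , drop = FALSE],
                          augmentation[shared, , drop = FALSE]),
                    scale_tag = scale_tag(study))
}

#' Extract the primary/recurrent pairing from study metadata
#'
#' @param meta metadata data.frame
#' @return data.frame patient_id, primary, recurrent (one row per patient
#'   with both tissue classes)
#' @export
study_pairing <- function(meta) {
  st <- meta[meta$cohort == "study", , drop = FALSE]
  patients <- unique(st$patient_id)
  rows <- lapply(patients, function(p) {
    sub <- st[st$patient_id == p, , drop = FALSE]
    prim <- sub$sample_id[sub$tissue_class == "primary"]
    rec <- sub$sample_id[sub$tissue_class == "recurrent"]
    if (length(prim) != 1 || length(rec) != 1) return(NULL)
    data.frame(patient_id = p, primary = prim, recurrent = rec)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no complete primary/recurrent pair in metadata")
  do.call(rbind, rows)
}
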