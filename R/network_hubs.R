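## Hub-gene ranking on a protein-protein interaction network by Maximal
## Clique Centrality: MCC(v) = sum over maximal cliques C containing v of
## (|C| - 1)!. With no edges among v's neighbors every incident edge is its
## own maximal 2-clique, so the score reduces to deg(v). Clique enumeration
## is exact (Bron-Kerbosch with pivoting via igraph); fine for DEG-scale
## subnetworks (~160 nodes), guarded against accidental huge inputs.

#' Build a simple undirected graph from an edge list
#'
#' @param edges data.frame gene_a, gene_b (optional score); self-loops are an
#'   error, duplicate edges are collapsed
#' @param nodes optional node set including isolated genes
#' @return igraph graph
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  if (any(edges$gene_a == edges$gene_b)) {
    bad <- edges$gene_a[edges$gene_a == edges$gene_b]
    stop("self-loop(s) on: ", paste(unique(bad), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = nodes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Enumerate maximal cliques
#'
#' Exact enumeration (size >= 2); each maximal clique returned once as a
#' character vector of node names.
#'
#' @param g igraph graph (simple, undirected)
#' @param max_nodes hard guard on node count
#' @return list of character vectors
#' @export
maximal_cliques <- function(g, max_nodes = 5000) {
  n <- igraph::vcount(g)
  if (n > max_nodes) stop(sprintf("graph has %d nodes (> guard of %d)", n, max_nodes))
  if (n > 500) {
    ps_log(sprintf("maximal_cliques: %d nodes; clique enumeration may be slow", n),
           stage = "network_hubs")
  }
  if (any(igraph::which_loop(g))) stop("graph has self-loop(s)")
  cl <- igraph::max_cliques(g, min = 2)
  lapply(cl, function(v) sort(igraph::V(g)$name[v]))
}

#' Maximal Clique Centrality scores
#'
#' @param g igraph graph
#' @param cliques optional precomputed clique list from [maximal_cliques()]
#' @return data.frame gene, mcc, degree; isolated nodes score 0 (logged)
#' @export
mcc_scores <- function(g, cliques = NULL) {
  if (is.null(cliques)) cliques <- maximal_cliques(g)
  nodes <- igraph::V(g)$name
  score <- stats::setNames(numeric(length(nodes)), nodes)
  for (cl in cliques) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  deg <- igraph::degree(g)[nodes]
  isolated <- nodes[deg == 0]
  if (length(isolated)) {
    ps_log(sprintf("mcc_scores: %d isolated node(s) score 0", length(isolated)),
           stage = "network_hubs")
  }
  data.frame(gene = nodes, mcc = unname(score), degree = unname(deg),
             stringsAsFactors = FALSE)
}

#' Top-k hub genes
#'
#' Ranks by MCC descending, ties by degree descending then gene id.
#'
#' @param scores data.frame from [mcc_scores()]
#' @param k number of hubs
#' @return data.frame gene, mcc, degree, rank
#' @export
top_k_hubs <- function(scores, k = 10) {
  if (k > nrow(scores)) stop(sprintf("k = %d exceeds node count %d", k, nrow(scores)))
  ord <- order(-scores$mcc, -scores$degree, scores$gene)
  out <- scores[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}
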