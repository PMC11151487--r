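## Independent oracles: deliberately naive implementations-by-definition,
## kept free of any package internals so they can certify the fast paths.

## Benjamini-Hochberg by the literal step-up definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[ord][i:m] / (i:m))
  }
  pmin(1, q_sorted)[order(ord)]
}

## Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
brute_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## All maximal cliques (size >= 2) of an adjacency matrix, by checking every
## vertex subset for clique-ness and maximality.
brute_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  out <- list()
  for (s in seq_len(2^n - 1)) {
    members <- which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    sub <- adj[members, members, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next
    outside <- setdiff(seq_len(n), members)
    maximal <- !any(vapply(outside, function(w) all(adj[w, members] == 1), TRUE))
    if (maximal) out[[length(out) + 1]] <- sort(nodes[members])
  }
  out
}

brute_mcc <- function(adj) {
  cl <- brute_max_cliques(adj)
  score <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (c_ in cl) score[c_] <- score[c_] + factorial(length(c_) - 1)
  score
}

random_adjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(0L, n, n, dimnames = list(paste0("v", seq_len(n)),
                                          paste0("v", seq_len(n))))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

adjacency_to_edges <- function(adj) {
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  data.frame(gene_a = rownames(adj)[idx[, 1]],
             gene_b = rownames(adj)[idx[, 2]],
             score = NA_real_, stringsAsFactors = FALSE)
}

## geNorm stability by the direct pairwise formula, computed independently.
brute_genorm_m <- function(log2_expr) {
  n <- nrow(log2_expr)
  vapply(seq_len(n), function(j) {
    others <- setdiff(seq_len(n), j)
    mean(vapply(others, function(k) {
      ratio <- log2_expr[j, ] - log2_expr[k, ]
      sqrt(sum((ratio - mean(ratio))^2) / (length(ratio) - 1))
    }, 0))
  }, 0)
}

## Exact Shapley values by enumeration over all 2^G coalitions, with the
## coalition value v(S) = mean over background rows of f(x_S, bg_rest).
exact_shapley <- function(net, xA, xB, bgA, bgB) {
  G <- length(xA)
  m <- nrow(bgA)
  coalition_value <- function(mask) {
    A <- bgA; B <- bgB
    for (g in which(mask)) {
      A[, g] <- xA[g]
      B[, g] <- xB[g]
    }
    mean(pathsig::predict_pairs(net, A, B))
  }
  v <- vapply(0:(2^G - 1), function(s) {
    coalition_value(bitwAnd(s, 2^(seq_len(G) - 1)) > 0)
  }, 0)
  phi <- numeric(G)
  for (g in seq_len(G)) {
    for (s in 0:(2^G - 1)) {
      if (bitwAnd(s, 2^(g - 1)) > 0) next
      size <- sum(bitwAnd(s, 2^(seq_len(G) - 1)) > 0)
      w <- factorial(size) * factorial(G - size - 1) / factorial(G)
      phi[g] <- phi[g] + w * (v[s + 2^(g - 1) + 1] - v[s + 1])
    }
  }
  phi
}

## A hand-built network whose PR logit is 100 + g1_a + g1_b: linear in gene
## 1 only (all activations stay in their linear region), ignoring the rest.
linear_gene1_net <- function(G) {
  spec <- pathsig::model_spec(G, conv_filters = 2, dense_units = c(2, 2),
                              epochs = 1)
  Wc <- matrix(0, 2, 2); Wc[1, ] <- 1          # filter 1: sums the pair slots
  W1 <- matrix(0, G * 2, 2); W1[1, 1] <- 1     # pick gene 1, filter 1
  W2 <- matrix(0, 2, 2); W2[1, 1] <- 1
  W3 <- matrix(0, 2, 2); W3[1, 2] <- 1         # feed the PR logit only
  list(Wc = Wc, bc = c(100, 0), W1 = W1, b1 = c(0, 0), W2 = W2, b2 = c(0, 0),
       W3 = W3, b3 = c(0, 0), spec = spec)
}

## Small standardized cohort with a planted class shift, for classifier and
## consensus tests. Returns the matrix, ids and the planted genes.
make_signal_cohort <- function(n_genes = 20, n_primary = 20, n_recurrent = 8,
                               n_signal = 5, shift = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  prim <- sprintf("prim%02d", seq_len(n_primary))
  rec <- sprintf("rec%02d", seq_len(n_recurrent))
  mat <- matrix(stats::rnorm(n_genes * (n_primary + n_recurrent)), n_genes,
                dimnames = list(genes, c(prim, rec)))
  signal <- genes[seq_len(n_signal)]
  mat[signal, rec] <- mat[signal, rec] + shift
  list(mat = mat, primary = prim, recurrent = rec, signal = signal)
}

complete_graph_edges <- function(n) {
  v <- sprintf("n%02d", seq_len(n))
  e <- t(utils::combn(v, 2))
  data.frame(gene_a = e[, 1], gene_b = e[, 2], score = NA_real_)
}

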