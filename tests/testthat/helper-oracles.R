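# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths.

# Pearson correlation from the textbook sum formula.
bf_pearson <- function(u, v) {
  n <- length(u)
  num <- n * sum(u * v) - sum(u) * sum(v)
  den <- sqrt(n * sum(u^2) - sum(u)^2) * sqrt(n * sum(v^2) - sum(v)^2)
  num / den
}

# Modularity from the E-matrix definition: e_ii = fraction of edges inside
# module i, cross edges split half per incident module (so that
# s_i = sum_j e_ij equals module i's share of edge ends), Q = sum_i (e_ii - s_i^2).
bf_modularity <- function(adj, membership) {
  mods <- sort(unique(membership))
  U <- length(mods)
  E <- matrix(0, U, U)
  n_edge <- 0
  p <- nrow(adj)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (adj[i, j] == 1) {
      n_edge <- n_edge + 1
      a <- match(membership[i], mods)
      b <- match(membership[j], mods)
      if (a == b) {
        E[a, a] <- E[a, a] + 1
      } else {
        E[a, b] <- E[a, b] + 0.5
        E[b, a] <- E[b, a] + 0.5
      }
    }
  }
  E <- E / n_edge
  s <- rowSums(E)
  sum(diag(E) - s^2)
}

# Node-wise Jaccard through explicit set arithmetic.
bf_node_jaccard <- function(a, b, node) {
  ma <- names(a)[a == a[[node]]]
  mb <- names(b)[b == b[[node]]]
  length(intersect(ma, mb)) / length(union(ma, mb))
}

bf_agreement <- function(a, b) {
  mean(vapply(names(a), function(n) bf_node_jaccard(a, b, n), numeric(1)))
}

# Adjusted Rand index by explicit pair counting over all node pairs.
bf_ari <- function(a, b) {
  b <- b[names(a)]
  p <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  n_pairs <- p * (p - 1) / 2
  idx <- s11
  exp_idx <- (s11 + s10) * (s11 + s01) / n_pairs
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(0)
  (idx - exp_idx) / (max_idx - exp_idx)
}

random_partition <- function(p, k, labels = paste0("n", seq_len(p))) {
  out <- sample.int(k, p, replace = TRUE)
  names(out) <- labels
  out
}

# A small named graph from an edge list on labels n1..np.
toy_graph <- function(p, edges) {
  g <- igraph::make_empty_graph(p, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(p)))
  if (length(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  g
}
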