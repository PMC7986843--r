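check_membership <- function(membership, g = NULL) {
  if (is.null(names(membership)))
    stop("a module membership vector must be named by node label")
  if (anyNA(membership)) stop("membership contains NA")
  if (!is.null(g)) {
    if (!setequal(names(membership), igraph::V(g)$name))
      stop("membership labels do not match the graph's node set")
    membership <- membership[igraph::V(g)$name]
  }
  membership
}

#' Modularity of a partition (Newman-Girvan Q)
#'
#' Q = sum_i (e_ii - s_i^2), where e_ij is the fraction of edges joining
#' module i to module j (within-module edges counted in e_ii) and
#' s_i = sum_j e_ij is the fraction of edge ends attached to module i.
#' Q > 0 indicates more within-module edges than a degree-matched random
#' graph would give; Q <= 0 indicates no structure beyond chance.
#' Isolated nodes touch no edges and contribute nothing.
#'
#' @param g igraph undirected graph with at least one edge.
#' @param membership named integer vector assigning each node to a module.
#' @return modularity in \[-1, 1\].
#' @export
graph_modularity <- function(g, membership) {
  membership <- check_membership(membership, g)
  n_edge <- igraph::ecount(g)
  if (n_edge == 0L)
    stop("modularity undefined on an edgeless graph (no edges to apportion)")
  ends <- igraph::as_edgelist(g, names = TRUE)
  ma <- membership[ends[, 1L]]
  mb <- membership[ends[, 2L]]
  e_within <- sum(ma == mb) / n_edge
  # s_i: half of each edge's two ends per incident module
  ends_per_module <- tabulate(c(match(ma, unique(membership)),
                                match(mb, unique(membership))),
                              nbins = length(unique(membership)))
  s <- ends_per_module / (2 * n_edge)
  e_within - sum(s^2)
}

relabel_by_size <- function(membership) {
  sizes <- table(membership)
  # decreasing size, ties by first appearance in node order
  first_seen <- vapply(names(sizes), function(k) match(k, as.character(membership)),
                       integer(1))
  ord <- order(-as.integer(sizes), first_seen)
  new_id <- seq_along(ord)
  names(new_id) <- names(sizes)[ord]
  out <- new_id[as.character(membership)]
  names(out) <- names(membership)
  out
}

#' Detect modules by fast-greedy modularity optimization
#'
#' Agglomerative Clauset-Newman-Moore optimization of modularity: starting
#' from singletons, communities are repeatedly merged by the largest gain in
#' Q and the merge dendrogram is cut at its Q maximum
#' (via [igraph::cluster_fast_greedy()], which is deterministic for a fixed
#' graph). An edgeless graph returns the all-singleton partition rather than
#' erroring: with no edges every node is its own module. Isolated nodes come
#' back as singleton modules.
#'
#' @param g igraph undirected simple graph; vertices must be named.
#' @return named integer membership vector in the graph's node order, module
#'   ids 1-based in decreasing module-size order.
#' @export
detect_modules <- function(g) {
  if (is.null(igraph::V(g)$name))
    stop("graph vertices must be named")
  labels <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    out <- seq_along(labels)
    names(out) <- labels
    return(out)
  }
  fg <- igraph::cluster_fast_greedy(g)
  membership <- igraph::membership(fg)
  membership <- as.integer(membership)
  names(membership) <- labels
  relabel_by_size(membership)
}

#' Split a membership vector into module node sets
#'
#' @param membership named membership vector.
#' @return list of character vectors of node labels, named by module id.
#' @export
module_members <- function(membership) {
  membership <- check_membership(membership)
  split(names(membership), membership)
}
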