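#' Degree-preserving randomization of a graph
#'
#' Rewires a graph by double-edge-swap MCMC: pairs of edges are repeatedly
#' swapped, rejecting swaps that would create self-loops or multi-edges, so
#' the per-node degree sequence (and the node order) is conserved exactly
#' while any module structure is destroyed. The default number of attempted
#' swaps is 10 |E|, the usual mixing heuristic.
#'
#' @param g igraph undirected simple graph.
#' @param nswap attempted swaps; default `10 * ecount(g)`.
#' @param seed optional integer seed.
#' @return a rewired igraph graph on the same vertices. Graphs with fewer
#'   than 2 edges are returned unchanged with a warning (no swap possible).
#' @export
rewire_degree_preserving <- function(g, nswap = 10 * igraph::ecount(g),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (igraph::ecount(g) < 2L) {
    warning("fewer than 2 edges: no degree-preserving swap possible, ",
            "returning the graph unchanged")
    return(g)
  }
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = nswap))
}

#' Expected stability under the structureless null
#'
#' Monte-Carlo estimate of the stability a graph of this degree sequence
#' would show with no module structure at all: m degree-preserving
#' randomizations of the graph are generated, modules are detected in each,
#' and the mean pairwise agreement among the m resulting partitions is
#' returned. This is the reference level the observed stability is compared
#' against in the gap-style profile.
#'
#' @param g igraph undirected graph (the reference graph at one threshold).
#' @param m number of null graphs, at least 2.
#' @param seed optional integer seed.
#' @return mean pairwise agreement among the m null partitions, in (0, 1\].
#' @export
null_expected_stability <- function(g, m, seed = NULL) {
  if (m < 2L) stop("need m >= 2 null graphs to form pairwise agreements")
  if (!is.null(seed)) set.seed(seed)
  parts <- vector("list", m)
  for (i in seq_len(m)) {
    gi <- suppressWarnings(rewire_degree_preserving(g))
    parts[[i]] <- detect_modules(gi)
  }
  observed_stability(parts)
}
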