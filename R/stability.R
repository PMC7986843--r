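#' Bootstrap resample of the observations
#'
#' Draws N rows with replacement from the data matrix; variables (columns)
#' stay fixed, which is the correct resampling scheme when nodes are
#' variables and the randomness comes from the sampled subjects.
#'
#' @param x data matrix.
#' @param seed optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return an N x p matrix of resampled rows with the original column names.
#' @export
bootstrap_resample <- function(x, seed = NULL) {
  x <- as_data_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
  x[idx, , drop = FALSE]
}

align_partitions <- function(a, b) {
  a <- check_membership(a)
  b <- check_membership(b)
  if (!setequal(names(a), names(b)))
    stop("the two partitions are not on the same node set")
  list(a = a, b = b[names(a)])
}

# Per-node Jaccard between the modules containing each node, via the
# contingency table of the two partitions: a node in cell (u, v) has
# Jaccard n_uv / (n_u. + n_.v - n_uv).
nodewise_jaccard <- function(a, b) {
  p <- align_partitions(a, b)
  fa <- match(p$a, unique(p$a))
  fb <- match(p$b, unique(p$b))
  ka <- max(fa); kb <- max(fb)
  ct <- matrix(tabulate((fa - 1L) * kb + fb, nbins = ka * kb),
               nrow = ka, ncol = kb, byrow = TRUE)
  na <- rowSums(ct)
  nb <- colSums(ct)
  J <- ct / (outer(na, nb, "+") - ct)
  out <- J[cbind(fa, fb)]
  names(out) <- names(p$a)
  out
}

#' Jaccard co-membership similarity of one node between two partitions
#'
#' Jaccard(M_a(n), M_b(n)) where M(n) is the module containing node n. Since
#' n belongs to both modules the value lies in (0, 1\]; it equals 1 iff the
#' two modules coincide.
#'
#' @param a,b named membership vectors on the same node set.
#' @param node node label.
#' @return Jaccard coefficient in (0, 1\].
#' @export
node_jaccard <- function(a, b, node) {
  p <- align_partitions(a, b)
  if (!node %in% names(p$a)) stop("unknown node label: ", node)
  ma <- names(p$a)[p$a == p$a[[node]]]
  mb <- names(p$b)[p$b == p$b[[node]]]
  length(intersect(ma, mb)) / length(union(ma, mb))
}

#' Mean node-wise Jaccard agreement between two partitions
#'
#' The agreement A(M_a, M_b) is the average over all p nodes of the Jaccard
#' similarity between the node's modules in the two partitions. Symmetric in
#' its arguments, in (0, 1\], and equal to 1 iff the partitions are identical.
#'
#' @param a,b named membership vectors on the same node set.
#' @return agreement in (0, 1\].
#' @export
partition_agreement <- function(a, b) {
  mean(nodewise_jaccard(a, b))
}

#' Unconditional observed stability of a set of partitions
#'
#' The mean pairwise agreement over all B + 1 partitions (the reference and
#' its bootstrap replicates alike); by symmetry of the agreement, the mean
#' over ordered pairs equals the mean over unordered pairs. Unlike the
#' conditional stabilities it treats all partitions symmetrically, which is
#' what makes it usable for threshold selection.
#'
#' @param partitions list of at least two named membership vectors on a
#'   common node set.
#' @return mean pairwise agreement in (0, 1\].
#' @export
observed_stability <- function(partitions) {
  k <- length(partitions)
  if (k < 2L) stop("need at least 2 partitions")
  tot <- 0
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      tot <- tot + partition_agreement(partitions[[i]], partitions[[j]])
  tot / (k * (k - 1L) / 2)
}

#' Conditional stability of a reference partition under bootstrap replicates
#'
#' Given the reference module set M0 and B bootstrap module sets on the same
#' nodes, computes stability at three levels, all conditional on M0:
#' \describe{
#'   \item{node}{S_node(n) = mean over replicates of the Jaccard similarity
#'     between n's reference module and its module in the replicate.}
#'   \item{module}{S_module(M) = mean of S_node over the members of M.}
#'   \item{overall}{S_over = mean over replicates of the partition agreement
#'     with M0, identically the mean of S_node over all p nodes.}
#' }
#'
#' @param reference named membership vector (the reference module set M0).
#' @param replicates list of B named membership vectors on the same node set.
#' @return an object of class `"stability_report"` with elements
#'   `node_stability` (named numeric), `module_stability` (numeric indexed by
#'   module id), `overall`, `reference`, `B`.
#' @export
stability <- function(reference, replicates) {
  reference <- check_membership(reference)
  if (!length(replicates)) stop("need at least one bootstrap replicate (B >= 1)")
  B <- length(replicates)
  node_mat <- vapply(replicates, function(r) nodewise_jaccard(reference, r),
                     numeric(length(reference)))
  node_stab <- rowMeans(node_mat)
  names(node_stab) <- names(reference)
  mod_stab <- vapply(module_members(reference),
                     function(nodes) mean(node_stab[nodes]), numeric(1))
  structure(
    list(node_stability = node_stab,
         module_stability = mod_stab,
         overall = mean(node_stab),
         reference = reference,
         B = B),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Bootstrap module stability (conditional on the reference partition)\n")
  cat(sprintf("  nodes: %d   modules: %d   bootstrap replicates: %d\n",
              length(x$node_stability), length(x$module_stability), x$B))
  cat(sprintf("  overall stability: %.4f\n", x$overall))
  cat("  module stability:\n")
  m <- x$module_stability
  sizes <- table(x$reference)[names(m)]
  for (i in seq_along(m))
    cat(sprintf("    module %s (n = %d): %.4f\n",
                names(m)[i], as.integer(sizes[i]), m[i]))
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  cat(sprintf("Overall stability: %.4f over %d replicates\n",
              object$overall, object$B))
  cat("Node stability quartiles:\n")
  print(stats::quantile(object$node_stability))
  invisible(object)
}
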