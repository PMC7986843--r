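block_sizes <- function(p, n_modules) {
  if (n_modules < 1L || n_modules > p)
    stop("number of modules must be between 1 and p")
  sizes <- rep(p %/% n_modules, n_modules)
  r <- p %% n_modules
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' True block partition of the simulation model
#'
#' Nodes are split into `n_modules` contiguous blocks; when p is not
#' divisible the remainder is spread one node per block over the leading
#' blocks.
#'
#' @param p number of variables.
#' @param n_modules number of blocks.
#' @param labels optional node labels (default `V1..Vp`).
#' @return named membership vector (the ground-truth module set).
#' @export
block_partition <- function(p, n_modules, labels = paste0("V", seq_len(p))) {
  sizes <- block_sizes(p, n_modules)
  out <- rep(seq_along(sizes), sizes)
  names(out) <- labels
  out
}

#' Block-diagonal correlation matrix
#'
#' The ground-truth generator for the simulations: unit diagonal, a constant
#' within-block correlation `alpha` on the diagonal blocks, and a constant
#' between-block correlation `beta` elsewhere, with 0 <= beta < alpha < 1 so
#' that some threshold in \[beta, alpha) exactly separates the blocks.
#' Positive definiteness is verified via the smallest eigenvalue.
#'
#' @param p number of variables.
#' @param n_modules number of equal (up to remainder) diagonal blocks.
#' @param alpha within-block correlation.
#' @param beta between-block correlation, `0 <= beta < alpha < 1`.
#' @param labels optional node labels.
#' @return p x p correlation matrix with block structure.
#' @examples
#' block_correlation(4, 2, alpha = 0.5, beta = 0.1)
#' @export
block_correlation <- function(p, n_modules, alpha, beta,
                              labels = paste0("V", seq_len(p))) {
  if (!(beta >= 0 && beta < alpha && alpha < 1))
    stop("need 0 <= beta < alpha < 1 for a separable block model")
  blocks <- block_partition(p, n_modules, labels)
  same <- outer(blocks, blocks, "==")
  C <- ifelse(same, alpha, beta)
  diag(C) <- 1
  dimnames(C) <- list(labels, labels)
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop(sprintf("block model is not positive definite (smallest eigenvalue %.3g)",
                 ev_min))
  C
}

#' Sample Gaussian data with a given correlation structure
#'
#' N independent draws from a zero-mean multivariate normal with covariance
#' equal to the (unit-variance) correlation matrix, via [MASS::mvrnorm()].
#'
#' @param C positive-definite correlation matrix.
#' @param N sample size.
#' @param seed optional integer seed.
#' @return N x p data matrix with C's variable names as column names.
#' @export
sample_gaussian <- function(C, N, seed = NULL) {
  C <- check_correlation_matrix(C)
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop(sprintf("correlation matrix is not positive definite (smallest eigenvalue %.3g)",
                 ev_min))
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(N, mu = rep(0, ncol(C)), Sigma = C)
  if (N == 1L) x <- matrix(x, nrow = 1L)
  colnames(x) <- colnames(C)
  x
}

#' Sample Gaussian data Markov to a given graph
#'
#' Generic plumbing for graph-based studies: builds a precision matrix with
#' the graph's sparsity pattern (off-diagonal -w on edges, diagonal
#' 1 + w * degree, diagonally dominant hence always positive definite),
#' inverts it, rescales to unit variances, and samples N multivariate-normal
#' rows. Conditional independence holds exactly for non-adjacent pairs.
#'
#' @param g igraph undirected graph with named vertices.
#' @param N sample size.
#' @param w edge weight in the precision matrix (default 0.3); larger w gives
#'   stronger marginal correlations along edges.
#' @param seed optional integer seed.
#' @return N x p data matrix, columns in the graph's node order.
#' @export
ggm_sample <- function(g, N, w = 0.3, seed = NULL) {
  if (is.null(igraph::V(g)$name)) stop("graph vertices must be named")
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  P <- -w * A
  diag(P) <- 1 + w * igraph::degree(g)
  S <- solve(P)
  S <- stats::cov2cor(S)
  dimnames(S) <- list(igraph::V(g)$name, igraph::V(g)$name)
  sample_gaussian(S, N, seed = seed)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement ([mclust::adjustedRandIndex()]):
#' 1 for identical partitions (up to relabeling), near 0 for independent
#' ones. Symmetric.
#'
#' @param a,b named membership vectors on the same node set.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  p <- align_partitions(a, b)
  mclust::adjustedRandIndex(p$a, p$b)
}

#' Run one block-model recovery experiment
#'
#' Simulates Gaussian data from the block-diagonal correlation model, fits
#' the full [stability_profile()], detects modules at the selected threshold,
#' and scores recovery of the true block partition by ARI. The Bonferroni
#' p-value graph baseline is run on the same data with the same module
#' detection, so the comparison isolates the graph-construction rule.
#'
#' @param p,n_modules,alpha,beta block-model parameters
#'   (see [block_correlation()]).
#' @param N sample size.
#' @param thresholds,B,m profile settings (see [stability_profile()]).
#' @param seed master seed; data simulation and the profile use separate
#'   substreams derived from it.
#' @param level significance level for the p-value baseline.
#' @return object of class `"block_experiment"`: `t_opt`,
#'   `n_modules_detected`, `ari_stability`, `ari_pvalue`, the fitted
#'   `profile`, the detected `modules`, and the `truth` partition.
#' @export
run_block_experiment <- function(p = 100, n_modules = 10, alpha, beta = 0.1,
                                 N,
                                 thresholds = seq(0.30, 0.90, by = 0.05),
                                 B = 100, m = 50, seed = NULL,
                                 level = 0.05) {
  ss <- derive_seeds(2L, seed)
  C <- block_correlation(p, n_modules, alpha, beta)
  truth <- block_partition(p, n_modules)
  x <- sample_gaussian(C, N, seed = ss[1L])
  fit <- stability_profile(x, thresholds = thresholds, B = B, m = m,
                           seed = ss[2L], keep_reports = FALSE)
  modules <- fit$modules_opt
  baseline <- detect_modules(pvalue_graph(x, level = level))
  structure(
    list(t_opt = fit$t_opt,
         n_modules_detected = length(unique(modules)),
         ari_stability = adjusted_rand(modules, truth),
         ari_pvalue = adjusted_rand(baseline, truth),
         profile = fit,
         modules = modules,
         truth = truth,
         params = list(p = p, n_modules = n_modules, alpha = alpha,
                       beta = beta, N = N, B = B, m = m, seed = seed)),
    class = "block_experiment")
}

#' @export
print.block_experiment <- function(x, ...) {
  with(x$params, cat(sprintf(
    "Block-model experiment: p = %d, %d modules, alpha = %.2f, beta = %.2f, N = %d\n",
    p, n_modules, alpha, beta, N)))
  cat(sprintf("  t_opt = %.3g with %d modules detected\n",
              x$t_opt, x$n_modules_detected))
  cat(sprintf("  ARI (stability-selected threshold): %.4f\n", x$ari_stability))
  cat(sprintf("  ARI (Bonferroni p-value baseline):  %.4f\n", x$ari_pvalue))
  invisible(x)
}

#' Sweep block-model simulation cells
#'
#' Runs [run_block_experiment()] over the cross product of the supplied
#' parameter vectors, `n_seeds` independent seeds per cell, and returns one
#' tidy row per run.
#'
#' @param N,alpha,p,n_modules,beta parameter vectors crossed into cells.
#' @param thresholds,B,m profile settings.
#' @param n_seeds replicate runs per cell.
#' @param seed master seed from which all per-run seeds derive.
#' @return data frame with columns `p`, `n_modules`, `alpha`, `beta`, `N`,
#'   `seed`, `t_opt`, `n_modules_detected`, `ari_stability`, `ari_pvalue`.
#' @export
simulation_sweep <- function(N, alpha, p = 100, n_modules = 10, beta = 0.1,
                             thresholds = seq(0.30, 0.90, by = 0.05),
                             B = 100, m = 50, n_seeds = 10, seed = NULL) {
  cells <- expand.grid(p = p, n_modules = n_modules, alpha = alpha,
                       beta = beta, N = N, rep = seq_len(n_seeds),
                       KEEP.OUT.ATTRS = FALSE)
  run_seeds <- derive_seeds(nrow(cells), seed)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    ex <- run_block_experiment(p = cc$p, n_modules = cc$n_modules,
                               alpha = cc$alpha, beta = cc$beta, N = cc$N,
                               thresholds = thresholds, B = B, m = m,
                               seed = run_seeds[i])
    data.frame(p = cc$p, n_modules = cc$n_modules, alpha = cc$alpha,
               beta = cc$beta, N = cc$N, seed = run_seeds[i],
               t_opt = ex$t_opt,
               n_modules_detected = ex$n_modules_detected,
               ari_stability = ex$ari_stability,
               ari_pvalue = ex$ari_pvalue)
  })
  do.call(rbind, rows)
}
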