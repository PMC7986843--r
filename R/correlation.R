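#' Validate a data matrix of observations by variables
#'
#' Checks the conventions used throughout the package: a numeric matrix with
#' N >= 3 observations in rows and p >= 2 uniquely named variables in columns.
#' Column order is the canonical node order for every graph built downstream.
#'
#' @param x numeric matrix or data frame, rows = observations, columns =
#'   variables; column names are the node labels.
#' @return the validated numeric matrix (data frames are coerced).
#' @export
as_data_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (observations x variables)")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("variable names must be unique")
  if (nrow(x) < 3L)
    stop("need at least 3 observations to define correlations and p-values")
  if (ncol(x) < 2L)
    stop("need at least 2 variables")
  x
}

check_finite <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("missing or non-finite values in the data; impute or drop them first")
  invisible(x)
}

constant_columns <- function(x) {
  v <- apply(x, 2L, stats::var)
  colnames(x)[v == 0 | !is.finite(v)]
}

#' Pearson correlation matrix with validity checks
#'
#' Computes the p x p Pearson product-moment correlation matrix of a data
#' matrix. Constant columns make the correlation undefined and raise an error
#' naming the offending variables. The diagonal is set to exactly 1 and
#' entries are clamped to \[-1, 1\] against floating-point drift.
#'
#' @param x data matrix (see [as_data_matrix()]).
#' @param method correlation type; only `"pearson"` is supported and tested,
#'   the argument exists as the hook for alternative association measures.
#' @return symmetric p x p correlation matrix with unit diagonal, dimnames =
#'   variable names.
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' C <- correlation_matrix(x)
#' diag(C)
#' @export
correlation_matrix <- function(x, method = c("pearson")) {
  method <- match.arg(method)
  x <- as_data_matrix(x)
  check_finite(x)
  bad <- constant_columns(x)
  if (length(bad))
    stop("correlation undefined: constant column(s) ",
         paste(bad, collapse = ", "))
  C <- stats::cor(x, method = method)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  C
}

check_correlation_matrix <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("correlation matrix must be square")
  if (is.null(rownames(C))) {
    rownames(C) <- colnames(C) <- paste0("V", seq_len(ncol(C)))
  }
  if (max(abs(C - t(C))) > 1e-8) stop("correlation matrix must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-8)) stop("correlation matrix diagonal must be 1")
  if (any(abs(C) > 1 + 1e-8)) stop("correlation entries must lie in [-1, 1]")
  C
}

#' Threshold a correlation matrix into a binary graph
#'
#' Places an edge between distinct nodes i and j iff |C(i, j)| > t, with the
#' inequality strict: ties at exactly t are excluded. The node set and its
#' order are those of the correlation matrix; isolated nodes are kept, and
#' t >= 1 legally yields an edgeless graph.
#'
#' @param C correlation matrix (symmetric, unit diagonal).
#' @param t nonnegative absolute-correlation threshold.
#' @return an [igraph][igraph::igraph-package] undirected simple graph whose
#'   vertices carry the variable names in canonical order.
#' @export
threshold_graph <- function(C, t) {
  C <- check_correlation_matrix(C)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  A <- (abs(C) > t) * 1L
  diag(A) <- 0L
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Bonferroni p-value graph (baseline construction)
#'
#' The conventional alternative to hard thresholding: for every pair of
#' variables the two-sided p-value of the Pearson correlation is computed from
#' the t statistic r * sqrt((N - 2) / (1 - r^2)) on N - 2 degrees of freedom,
#' Bonferroni-adjusted by the p(p - 1)/2 tested pairs (capped at 1), and an
#' edge is placed where the adjusted p-value falls below `level`.
#'
#' @param x data matrix.
#' @param level significance level for the adjusted p-value (default 0.05).
#' @return an igraph undirected graph on the p variables.
#' @export
pvalue_graph <- function(x, level = 0.05) {
  x <- as_data_matrix(x)
  stopifnot(level > 0, level <= 1)
  N <- nrow(x)
  if (N < 3L) stop("need N >= 3 for the correlation t-test (df = N - 2 >= 1)")
  C <- correlation_matrix(x)
  p <- ncol(C)
  r <- C
  diag(r) <- 0
  tt <- abs(r) * sqrt((N - 2) / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- Inf
  pv <- 2 * stats::pt(tt, df = N - 2, lower.tail = FALSE)
  adj <- pmin(pv * p * (p - 1) / 2, 1)
  A <- (adj < level) * 1L
  diag(A) <- 0L
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}
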