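#' Read a data matrix from delimited text
#'
#' Rows are observations, columns are variables, the first row holds the
#' variable names.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return validated numeric matrix (see [as_data_matrix()]).
#' @export
read_data_matrix <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE)
  as_data_matrix(df)
}

#' Read a precomputed correlation matrix from delimited text
#'
#' Expects a header of variable names and, optionally, a leading column of
#' row names; the matrix must be square, symmetric with unit diagonal.
#'
#' @inheritParams read_data_matrix
#' @return validated correlation matrix.
#' @export
read_correlation_matrix <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE)
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  C <- as.matrix(df)
  if (is.null(rownames(C)) || all(rownames(C) == as.character(seq_len(nrow(C)))))
    rownames(C) <- colnames(C)
  check_correlation_matrix(C)
}

#' Write a graph as an edge list
#'
#' Two tab-separated label columns (`from`, `to`); isolated nodes do not
#' appear, so the companion module TSV is the full node roster.
#'
#' @param g igraph graph with named vertices.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(from = el[, 1L], to = el[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read module assignments as TSV
#'
#' Two columns: variable label and 1-based module id (ids are in decreasing
#' module-size order as produced by [detect_modules()]).
#'
#' @param membership named membership vector.
#' @param path file path.
#' @export
write_modules <- function(membership, path) {
  membership <- check_membership(membership)
  df <- data.frame(variable = names(membership),
                   module = as.integer(membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  out <- as.integer(df$module)
  names(out) <- df$variable
  out
}

#' Serialize a stability profile
#'
#' `write_profile_csv()` writes the per-threshold table
#' (threshold, s_obs, s_null, s_delta, n_edges, n_modules);
#' `write_profile_json()` adds t_opt and the run parameters.
#'
#' @param fit a fitted [stability_profile()].
#' @param path file path.
#' @export
write_profile_csv <- function(fit, path) {
  stopifnot(inherits(fit, "stability_profile"))
  utils::write.csv(fit$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_profile_json <- function(fit, path) {
  stopifnot(inherits(fit, "stability_profile"))
  jsonlite::write_json(
    list(profile = fit$profile, t_opt = fit$t_opt,
         B = fit$B, m = fit$m, seed = fit$seed, N = fit$N, p = fit$p),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Serialize a conditional stability report
#'
#' JSON carries the node map, module map, overall stability, B and the seed;
#' the TSV is per node: label, reference module, node stability.
#'
#' @param report a [stability()] report.
#' @param path file path.
#' @param seed optional seed recorded in the JSON.
#' @export
write_stability_json <- function(report, path, seed = NULL) {
  stopifnot(inherits(report, "stability_report"))
  jsonlite::write_json(
    list(node_stability = as.list(report$node_stability),
         module_stability = as.list(report$module_stability),
         overall = report$overall, B = report$B, seed = seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stability_json
#' @export
write_stability_tsv <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  df <- data.frame(variable = names(report$node_stability),
                   module = as.integer(report$reference[names(report$node_stability)]),
                   stability = unname(report$node_stability))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
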