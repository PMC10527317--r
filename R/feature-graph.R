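# Pearson-correlation feature graph: nodes are indicators, edges connect
# pairs whose absolute training-set correlation exceeds a threshold.

#' Build the indicator correlation graph
#'
#' Computes the Pearson correlation between every indicator pair over the
#' training samples and keeps an (undirected, unweighted) edge wherever
#' `|r| > threshold`. Constant columns have undefined correlation and
#' produce no edges.
#'
#' @param train_table a [feature_table()] of training samples with no
#'   missing values (run [preprocess_pb()] first).
#' @param threshold absolute-correlation edge threshold in `[0, 1)`
#'   (default 0.3).
#' @return an object of class `feature_graph` with fields `n_nodes`,
#'   `edges` (m x 2 matrix, `i < j`, each pair stored once), `correlation`
#'   (per-edge r) and `feature_names`.
#' @export
build_feature_graph <- function(train_table, threshold = 0.3) {
  stopifnot(inherits(train_table, "feature_table"))
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  X <- train_table$values
  if (nrow(X) < 3L) stop("need at least 3 training samples")
  if (any(!is.finite(X))) stop("table has missing values; impute first")
  p <- ncol(X)
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0               # constant columns -> no edges
  keep <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
  edges <- matrix(keep, ncol = 2L)
  colnames(edges) <- c("i", "j")
  structure(list(n_nodes = p,
                 edges = edges,
                 correlation = R[keep],
                 feature_names = train_table$feature_names,
                 threshold = threshold),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat("<feature_graph> ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges (|r| > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

# Sparse neighbor-mean operator: row i averages the states of i's neighbors
# (excluding i itself); isolated nodes get a zero row.
graph_mean_operator <- function(graph) {
  n <- graph$n_nodes
  if (nrow(graph$edges) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  }
  ii <- c(graph$edges[, 1L], graph$edges[, 2L])
  jj <- c(graph$edges[, 2L], graph$edges[, 1L])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = scale) %*% A
}

#' Write a graph edge list as TSV
#'
#' Columns `i`, `j` (indicator names) and `r` (Pearson correlation).
#'
#' @param graph a [build_feature_graph()] result.
#' @param path output file.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(i = graph$feature_names[graph$edges[, 1L]],
                   j = graph$feature_names[graph$edges[, 2L]],
                   r = graph$correlation)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
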