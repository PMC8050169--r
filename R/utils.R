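# Internal helpers shared across modules.

#' Enumerate unordered node pairs
#'
#' Upper-triangle (i < j) edge enumeration for an undirected graph on
#' `n` nodes, in lexicographic order.
#'
#' @param n Number of nodes.
#' @return A data frame with integer columns `i` and `j`, one row per
#'   possible edge, `n * (n - 1) / 2` rows in total.
#' @keywords internal
upper_tri_pairs <- function(n) {
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  # column-major which() yields j-major order; re-sort lexicographically by (i, j)
  ord <- order(idx[, "row"], idx[, "col"])
  data.frame(i = idx[ord, "row"], j = idx[ord, "col"])
}

n_possible_edges <- function(n) as.numeric(n) * (n - 1) / 2

# Extract upper-triangle values of a symmetric matrix in (i < j) lexicographic order.
ut_values <- function(m) {
  n <- nrow(m)
  p <- upper_tri_pairs(n)
  m[cbind(p$i, p$j)]
}

# Rebuild a symmetric matrix (zero diagonal) from upper-triangle values in
# the order produced by upper_tri_pairs().
ut_matrix <- function(values, n) {
  p <- upper_tri_pairs(n)
  m <- matrix(0, n, n)
  m[cbind(p$i, p$j)] <- values
  m[cbind(p$j, p$i)] <- values
  m
}

assert_symmetric_zero_diag <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    stop(what, " must have a zero diagonal", call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12, check.attributes = FALSE))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
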