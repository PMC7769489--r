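pad_cols <- function(mat, k) {
  n <- ncol(mat)
  if (n >= k) mat[, seq_len(k), drop = FALSE]
  else cbind(mat, mat[, rep(n, k - n), drop = FALSE])
}

esec_mat <- function(x) if (inherits(x, "esec_matrix")) x$mat else as.matrix(x)

#' Similarity between two eSEC matrices
#'
#' The shorter matrix is right-padded by repeating its last column so both
#' have `k = max(n, m)` columns. For every pair row and column, the three
#' relation categories (TNR, SSR, DSR) are compared; the compound difference
#' of a cell is the number of differing categories divided by 3. The total
#' dissimilarity D is the mean compound difference over the `10 x k` cells,
#' and the similarity is `(1 - D) * 100` percent.
#'
#' @param A,B `esec_matrix` objects (or bare 30-row character matrices).
#' @param breakdown If `TRUE`, return the full similarity breakdown instead
#'   of the percentage alone.
#' @return Similarity in percent, or (with `breakdown = TRUE`) a list with
#'   the per-cell compound differences `d` (10 x k), total dissimilarity `D`,
#'   `similarity` and padded length `k`.
#' @export
esec_similarity <- function(A, B, breakdown = FALSE) {
  a <- esec_mat(A); b <- esec_mat(B)
  if (nrow(a) != 30L || nrow(b) != 30L)
    stop("domain error: eSEC matrices must have 30 rows")
  if (ncol(a) < 1L || ncol(b) < 1L)
    stop("domain error: empty eSEC matrix")
  k <- max(ncol(a), ncol(b))
  a <- pad_cols(a, k); b <- pad_cols(b, k)
  diffs <- a != b
  d <- (diffs[1:10, , drop = FALSE] + diffs[11:20, , drop = FALSE] +
          diffs[21:30, , drop = FALSE]) / 3
  D <- mean(d)
  sim <- (1 - D) * 100
  if (!breakdown) return(sim)
  list(d = d, D = D, similarity = sim, k = k)
}

#' Predictive power of a prediction column
#'
#' The percentage of an action's eSEC columns spared after the column at
#' which the observer committed to a label: `(1 - col/total) * 100`.
#'
#' @param prediction_column 1-based column at which the action was predicted.
#' @param total_columns Total number of eSEC columns of the action.
#' @return Percentage in `[0, 100)`.
#' @export
predictive_power <- function(prediction_column, total_columns) {
  if (any(prediction_column < 1L) || any(prediction_column > total_columns))
    stop("domain error: prediction column out of range")
  (1 - prediction_column / total_columns) * 100
}
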