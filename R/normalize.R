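#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the reference distribution is the vector of row means of the
#' column-sorted matrix, and each column's values are replaced by the
#' reference value at their rank. Ties within a column receive the mean of
#' the tied reference positions (dialects differ here; this is the
#' rank-run-mean convention, stated explicitly because it affects tied
#' probes). Within each column the rank order of features is preserved.
#'
#' @param m An expression tibble (see [as_expression()]); any scale.
#' @return The normalized expression tibble, same scale flag.
#' @export
#' @examples
#' m <- as_expression(tibble::tibble(id = c("a", "b"), s1 = c(1, 3), s2 = c(2, 4)))
#' quantile_normalize(m)  # both columns become (1.5, 3.5)
quantile_normalize <- function(m) {
  m <- as_expression(m, expr_scale(m))
  x <- expr_matrix(m)
  if (ncol(x) < 2L) {
    stop_mirlink("Quantile normalization needs >= 2 samples.", "mirlink_invalid_design")
  }
  ref <- rowMeans(matrix(apply(x, 2L, sort), nrow = nrow(x)))
  out <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    o <- order(col)
    sorted <- col[o]
    run <- cumsum(c(TRUE, sorted[-1L] != sorted[-length(sorted)]))
    col[o] <- stats::ave(ref, run, FUN = mean)
    col
  }, numeric(nrow(x)))
  dim(out) <- dim(x)
  colnames(out) <- colnames(x)
  rownames(out) <- rownames(x)
  as_expression(matrix_to_expr(out, names(m)[1L]), expr_scale(m))
}

#' Log2-transform a linear-scale expression matrix
#'
#' Applies `log2(x + offset)` if the table is flagged as linear scale;
#' idempotent on log2-flagged input. Nonpositive values after the offset
#' are a domain error.
#'
#' @param m An expression tibble.
#' @param offset Small constant added before the log (default 0).
#' @return A log2-flagged expression tibble.
#' @export
#' @examples
#' m <- as_expression(tibble::tibble(id = "a", s1 = 4, s2 = 8), "linear")
#' log2_if_linear(m)
log2_if_linear <- function(m, offset = 0) {
  m <- as_expression(m, expr_scale(m))
  if (expr_scale(m) == "log2") return(m)
  offset <- check_number(offset, "offset", 0)
  x <- expr_matrix(m) + offset
  if (any(x <= 0)) {
    stop_mirlink("Nonpositive intensities after offset; cannot take log2.",
                 "mirlink_domain_error")
  }
  as_expression(matrix_to_expr(log2(x), names(m)[1L]), "log2")
}
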