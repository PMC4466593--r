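#' Mark a feature-by-sample table as an expression matrix
#'
#' Expression tables are ordinary tibbles whose first column holds unique
#' feature ids and whose remaining columns are one numeric column per sample.
#' The intensity scale (`"log2"` or `"linear"`) travels as an attribute so
#' that [log2_if_linear()] can be idempotent.
#'
#' @param x A data frame in feature-by-sample layout.
#' @param scale `"log2"` or `"linear"`.
#' @return A tibble with the `expr_scale` attribute set.
#' @export
#' @examples
#' m <- as_expression(tibble::tibble(feature_id = c("g1", "g2"),
#'                                   s1 = c(4, 8), s2 = c(2, 16)),
#'                    scale = "linear")
#' expr_scale(m)
as_expression <- function(x, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop_mirlink("An expression table needs an id column plus >= 1 sample column.",
                 "mirlink_schema_error")
  }
  x <- as_tibble(x)
  if (anyDuplicated(x[[1L]])) {
    stop_mirlink("Duplicate feature ids in expression table.", "mirlink_schema_error")
  }
  vals <- x[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop_mirlink("All sample columns must be numeric.", "mirlink_schema_error")
  }
  if (anyNA(vals)) {
    stop_mirlink("Expression table contains missing values; imputation is out of scope.",
                 "mirlink_validation_error")
  }
  attr(x, "expr_scale") <- scale
  x
}

#' @rdname as_expression
#' @export
expr_scale <- function(x) attr(x, "expr_scale") %||% "log2"
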