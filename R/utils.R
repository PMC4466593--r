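# Internal validation helpers. All user-facing errors go through rlang::abort
# with a class so tests can assert on the condition, not the message.

stop_mirlink <- function(msg, class, ...) {
  abort(msg, class = c(class, "mirlink_error"), ...)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    stop_mirlink(
      sprintf("`%s` must be a single integer >= %d (got %s).", name, min, deparse(x)),
      "mirlink_invalid_argument"
    )
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_mirlink(
      sprintf("`%s` must be a single number in [0, 1].", name),
      "mirlink_invalid_argument"
    )
  }
  as.numeric(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    stop_mirlink(
      sprintf("`%s` must be a single number %s %s.", name,
              if (strict) ">" else ">=", format(min)),
      "mirlink_invalid_argument"
    )
  }
  as.numeric(x)
}

# sample columns of an expression table (everything but the id column)
sample_cols <- function(expr) setdiff(names(expr), names(expr)[1L])

# numeric matrix view of an expression tibble, feature ids as rownames
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(expr[[1L]])
  m
}

# rebuild a tibble from a matrix, keeping the original id column name
matrix_to_expr <- function(m, id_col = "feature_id") {
  out <- as_tibble(as.data.frame(m))
  out <- tibble(!!id_col := rownames(m), !!!out)
  out
}

# stable fingerprint of a configuration list (used in metadata headers and
# cross-stage consistency checks)
config_fingerprint <- function(x) {
  flat <- unlist(x, use.names = TRUE)
  flat <- flat[order(names(flat))]
  rlang::hash(paste(names(flat), as.character(flat), sep = "=", collapse = ";"))
}
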