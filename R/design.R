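#' Build a balanced or unbalanced two-group sample design
#'
#' Returns the ordered sample sheet for a young-vs-adult comparison. Each
#' group needs at least two samples so that a within-group variance exists
#' for the per-feature ANOVA.
#'
#' @param n_young,n_adult Samples per group; both >= 2.
#' @return A tibble with columns `sample_id` and `group` (factor with levels
#'   `young`, `adult`), young samples first.
#' @export
#' @examples
#' generate_design(4, 4)
generate_design <- function(n_young = 4, n_adult = 4) {
  n_young <- check_count(n_young, "n_young", 0L)
  n_adult <- check_count(n_adult, "n_adult", 0L)
  if (n_young < 2L || n_adult < 2L) {
    stop_mirlink(
      "Each group needs >= 2 samples (within-group variance is undefined otherwise).",
      "mirlink_invalid_design"
    )
  }
  tibble(
    sample_id = c(sprintf("young_%d", seq_len(n_young)),
                  sprintf("adult_%d", seq_len(n_adult))),
    group = factor(rep(c("young", "adult"), c(n_young, n_adult)),
                   levels = c("young", "adult"))
  )
}

# validate a design tibble and an expression table against each other
check_design <- function(design, expr = NULL) {
  if (!is.data.frame(design) || !all(c("sample_id", "group") %in% names(design))) {
    stop_mirlink("`design` must have columns sample_id and group.", "mirlink_schema_error")
  }
  design <- as_tibble(design)
  design$group <- factor(as.character(design$group), levels = c("young", "adult"))
  if (anyNA(design$group)) {
    stop_mirlink("`design$group` must only contain 'young' and 'adult'.",
                 "mirlink_schema_error")
  }
  if (anyDuplicated(design$sample_id)) {
    stop_mirlink("Duplicate sample ids in design.", "mirlink_schema_error")
  }
  if (any(table(design$group) < 2L)) {
    stop_mirlink("Each group needs >= 2 samples.", "mirlink_invalid_design")
  }
  if (!is.null(expr)) {
    missing <- setdiff(sample_cols(expr), design$sample_id)
    if (length(missing)) {
      stop_mirlink(
        sprintf("Sample(s) not declared in design: %s", paste(missing, collapse = ", ")),
        "mirlink_schema_error"
      )
    }
  }
  design
}
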