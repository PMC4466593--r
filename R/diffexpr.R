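#' Per-feature one-way ANOVA between two groups
#'
#' Computes, for every feature of a log2-scale expression table, the group
#' means, the log2 fold change (adult minus young), the one-way ANOVA F
#' statistic and its p-value, and the BH-adjusted p-value across all
#' features. With two groups the pooled-variance ANOVA F equals the square
#' of the equal-variance two-sample t statistic and the p-values coincide;
#' a Welch-type statistic is available behind `var_equal = FALSE` but the
#' pooled fit is the default.
#'
#' Features with zero variance in both groups and equal means carry no
#' evidence either way and are assigned `p = 1` (F is `NA`), so constant
#' spike-in rows pass through rather than erroring.
#'
#' @param m A log2-flagged expression tibble.
#' @param design Design tibble (`sample_id`, `group`); every sample column
#'   of `m` must be declared.
#' @param var_equal Pooled variance (classic one-way ANOVA, default) or
#'   Welch.
#' @return A tibble of class `"de_result"` with columns `feature_id`,
#'   `mean_young`, `mean_adult`, `log2fc`, `f_stat`, `p_raw`, `p_adj`.
#' @seealso [classify_de()] to apply list filters, [bh_adjust()]
#' @export
de_anova <- function(m, design, var_equal = TRUE) {
  m <- as_expression(m, expr_scale(m))
  if (expr_scale(m) != "log2") {
    stop_mirlink("Run log2_if_linear() first: ANOVA expects log2 intensities.",
                 "mirlink_validation_error")
  }
  design <- check_design(design, m)
  x <- expr_matrix(m)
  x <- x[, design$sample_id[design$sample_id %in% colnames(x)], drop = FALSE]
  grp <- design$group[match(colnames(x), design$sample_id)]
  if (nlevels(droplevels(grp)) != 2L) {
    stop_mirlink("Exactly two groups (young, adult) are required.",
                 "mirlink_invalid_design")
  }
  young <- x[, grp == "young", drop = FALSE]
  adult <- x[, grp == "adult", drop = FALSE]
  n1 <- ncol(young); n2 <- ncol(adult)
  m1 <- rowMeans(young); m2 <- rowMeans(adult)
  ss1 <- rowSums((young - m1)^2)
  ss2 <- rowSums((adult - m2)^2)
  if (var_equal) {
    df2 <- n1 + n2 - 2L
    msw <- (ss1 + ss2) / df2
    msb <- (n1 * n2 / (n1 + n2)) * (m2 - m1)^2  # between-group SS, df = 1
    f <- msb / msw
    p <- pf(f, 1L, df2, lower.tail = FALSE)
  } else {
    v1 <- ss1 / (n1 - 1L); v2 <- ss2 / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    f <- (m2 - m1)^2 / se2
    df2 <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- pf(f, 1L, df2, lower.tail = FALSE)
  }
  # zero variance everywhere: equal means -> no evidence (p = 1);
  # unequal means -> perfect separation (p = 0)
  degenerate <- !is.finite(f)
  if (any(degenerate)) {
    zero_all <- degenerate & (ss1 + ss2) == 0
    p[zero_all & (m2 == m1)] <- 1
    p[zero_all & (m2 != m1)] <- 0
    f[degenerate] <- NA_real_
  }
  out <- tibble(
    feature_id = rownames(x),
    mean_young = unname(m1),
    mean_adult = unname(m2),
    log2fc = unname(m2 - m1),
    f_stat = unname(f),
    p_raw = unname(p),
    p_adj = bh_adjust(unname(p))
  )
  structure(out, class = c("de_result", class(tibble())))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `adjusted_i = min over sorted j >= i of min(1, m * p_(j) / j)`, stable
#' under permutation of the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p)) {
    stop_mirlink("`p` must be numeric.", "mirlink_domain_error")
  }
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_mirlink("p-values must lie in [0, 1].", "mirlink_domain_error")
  }
  p.adjust(p, method = "BH")
}

#' Declare up- and down-regulated features
#'
#' Applies a [filter_spec()] to per-feature statistics: a feature is `up`
#' when it passes the p criterion (raw or BH-adjusted, per the filter) with
#' `log2fc > 0` and `abs(log2fc) >= log2(fc_threshold)`; symmetrically for
#' `down`; otherwise `ns`. A feature with `log2fc` exactly 0 is `ns`
#' regardless of p (no direction is assignable).
#'
#' @param stats A `de_result` from [de_anova()].
#' @param spec A [filter_spec()]; the defaults encode the published
#'   criteria (genes: BH-adjusted p < 0.01; miRNAs: 1.5-fold with raw
#'   p < 0.001).
#' @return The `de_result` with a `direction` column
#'   (`up`/`down`/`ns`); the filter is echoed in the `filter_spec` attribute.
#' @export
#' @examples
#' # a miRNA at fold change 1.41 (< 1.5) stays ns however small its p
classify_de <- function(stats, spec = filter_spec("gene")) {
  stopifnot(is.data.frame(stats), inherits(spec, "filter_spec"))
  needed <- c("feature_id", "log2fc", "p_raw", "p_adj")
  if (!all(needed %in% names(stats))) {
    stop_mirlink("`stats` must be a de_result (see de_anova()).", "mirlink_schema_error")
  }
  p_used <- if (spec$use_adjusted) stats$p_adj else stats$p_raw
  pass <- p_used < spec$p_threshold & abs(stats$log2fc) >= log2(spec$fc_threshold)
  stats$direction <- dplyr::case_when(
    pass & stats$log2fc > 0 ~ "up",
    pass & stats$log2fc < 0 ~ "down",
    .default = "ns"
  )
  structure(as_tibble(stats), filter_spec = spec,
            class = c("de_result", class(tibble())))
}

#' Extract declared feature sets from a classified `de_result`
#'
#' @param de A classified `de_result` (with a `direction` column).
#' @param direction `"up"` or `"down"`.
#' @return Sorted character vector of feature ids.
#' @export
de_features <- function(de, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!"direction" %in% names(de)) {
    stop_mirlink("Run classify_de() first.", "mirlink_validation_error")
  }
  sort(de$feature_id[de$direction == direction])
}
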