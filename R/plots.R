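# ggplot2 views of the main result types. Each autoplot() returns the
# ggplot object unevaluated so callers can restyle it.

#' Volcano plot of a differential-expression result
#'
#' @param object A (preferably classified) `de_result`.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 raw p, colored by declared
#'   direction.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object)
  if (!"direction" %in% names(df)) df$direction <- "ns"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_raw, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (adult - young)",
                  y = expression(-log[10] ~ "raw p"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of the top enriched sets
#'
#' @param object An `enrich_result`.
#' @param n_top Number of sets shown (by adjusted p).
#' @param ... Unused.
#' @return A ggplot: fold enrichment vs set, point size = overlap `k`,
#'   colour = -log10 adjusted p.
#' @export
autoplot.enrich_result <- function(object, n_top = 20, ...) {
  df <- head(as_tibble(object), n_top)
  df <- df[!is.na(df$fold_enrichment), , drop = FALSE]
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment, y = .data$name,
                                   size = .data$k,
                                   colour = -log10(pmax(.data$p_adj, 1e-300)))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment (k/n)/(K/N)", y = NULL,
                  colour = expression(-log[10] ~ "BH p"), size = "overlap k") +
    ggplot2::theme_minimal()
}

#' Degree distribution of hubs
#'
#' @param object A `hub_report`.
#' @param ... Unused.
#' @return A ggplot histogram of hub degrees, faceted by hub kind.
#' @export
autoplot.hub_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "distinct partners", y = "entities") +
    ggplot2::theme_minimal()
}
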