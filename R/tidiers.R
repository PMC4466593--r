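# broom-style tidiers: tidy() returns the per-unit table, glance() the
# one-row model-level summary.

#' @export
tidy.de_result <- function(x, ...) as_tibble(x)

#' @export
glance.de_result <- function(x, ...) {
  spec <- attr(x, "filter_spec")
  tibble(
    n_features = nrow(x),
    n_up = if ("direction" %in% names(x)) sum(x$direction == "up") else NA_integer_,
    n_down = if ("direction" %in% names(x)) sum(x$direction == "down") else NA_integer_,
    p_threshold = if (!is.null(spec)) spec$p_threshold else NA_real_,
    use_adjusted = if (!is.null(spec)) spec$use_adjusted else NA,
    fc_threshold = if (!is.null(spec)) spec$fc_threshold else NA_real_
  )
}

#' @export
tidy.enrich_result <- function(x, ...) as_tibble(x)

#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    family_size = attr(x, "family_size") %||% nrow(x),
    query_size = attr(x, "query_size") %||% NA_integer_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' @export
tidy.hub_report <- function(x, ...) as_tibble(x)

#' @export
glance.hub_report <- function(x, ...) {
  tibble(
    n_target_hubs = sum(x$kind == "target_hub"),
    n_mirna_hubs = sum(x$kind == "mirna_hub"),
    min_hub = attr(x, "min_hub") %||% NA_integer_
  )
}

#' @export
tidy.integration_summary <- function(x, ...) x$counts

#' @export
glance.integration_summary <- function(x, ...) {
  w <- tidyr::pivot_wider(x$counts,
                          names_from = c("block", "quantity"),
                          values_from = c("up", "down"),
                          names_glue = "{block}_{quantity}_{.value}")
  w$fingerprint <- x$fingerprint
  w
}

#' @export
tidy.mirlink_sim <- function(x, ...) {
  dplyr::bind_rows(
    tibble(id = x$truth$de_mirnas$mirna, role = "de_mirna",
           direction = x$truth$de_mirnas$direction, shift = x$truth$de_mirnas$shift),
    tibble(id = x$truth$de_genes_expected$gene, role = "de_gene_expected",
           direction = x$truth$de_genes_expected$direction,
           shift = x$truth$de_genes_expected$shift)
  )
}

#' @export
glance.mirlink_sim <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes), n_mirnas = nrow(x$mirnas),
    n_samples = nrow(x$design),
    n_de_mirnas = x$truth$n_de_mirnas,
    n_true_interactions = x$truth$n_true_interactions,
    n_interaction_records = nrow(x$interactions),
    n_gene_sets = nrow(x$gene_sets),
    seed = x$params$seed
  )
}
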