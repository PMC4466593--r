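#' Construct or load a multi-source miRNA-target interaction table
#'
#' An interaction table has one row per (miRNA, gene) pair, one 0/1 column
#' per prediction source, and an integer `support` column equal to the
#' number of flagging sources — a local, file-based stand-in for a
#' comparative target-prediction platform that aggregates several
#' algorithms. Duplicate pairs are merged by OR-ing their source flags and
#' recomputing support; a stored `support` value inconsistent with the
#' flags of its own row is a schema error.
#'
#' @param x A data frame with columns `mirna`, `gene`, the source columns
#'   and optionally `support`.
#' @param source_names Names of the source columns; by default every column
#'   other than `mirna`, `gene`, `support`.
#' @return A tibble of class `"interaction_tbl"`. Rows with no flagging
#'   source are dropped (a stored record must be supported at least once).
#' @seealso [consensus_filter()], [targets_of()], [find_hubs()]
#' @export
#' @examples
#' t <- as_interactions(tibble::tibble(
#'   mirna = c("m1", "m1"), gene = c("g1", "g1"),
#'   src_01 = c(1, 0), src_02 = c(0, 1)
#' ))
#' t$support  # OR-merged to a single record with support 2
as_interactions <- function(x, source_names = NULL) {
  if (!is.data.frame(x) || !all(c("mirna", "gene") %in% names(x))) {
    stop_mirlink("Interaction table needs `mirna` and `gene` columns.",
                 "mirlink_schema_error")
  }
  x <- as_tibble(x)
  source_names <- source_names %||% setdiff(names(x), c("mirna", "gene", "support"))
  if (length(source_names) == 0L) {
    stop_mirlink("Interaction table needs >= 1 source column.", "mirlink_schema_error")
  }
  missing_src <- setdiff(source_names, names(x))
  if (length(missing_src)) {
    stop_mirlink(sprintf("Source column(s) absent: %s", paste(missing_src, collapse = ", ")),
                 "mirlink_schema_error")
  }
  flags <- as.matrix(x[, source_names, drop = FALSE])
  if (!all(flags %in% c(0, 1))) {
    stop_mirlink("Source flags must be 0/1.", "mirlink_schema_error")
  }
  storage.mode(flags) <- "integer"
  if ("support" %in% names(x) && nrow(x)) {
    bad <- which(x$support != rowSums(flags))
    if (length(bad)) {
      stop_mirlink(
        sprintf("`support` disagrees with source flags at row(s) %s.",
                paste(head(bad, 5L), collapse = ", ")),
        "mirlink_schema_error"
      )
    }
  }
  out <- tibble(mirna = as.character(x$mirna), gene = as.character(x$gene))
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(flags)))
  # OR-merge duplicated pairs
  if (anyDuplicated(out[c("mirna", "gene")])) {
    out <- out |>
      dplyr::group_by(.data$mirna, .data$gene) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(source_names), ~ as.integer(any(.x > 0))),
                       .groups = "drop")
  }
  out$support <- as.integer(rowSums(out[, source_names, drop = FALSE]))
  out <- out[out$support > 0L, , drop = FALSE]
  out <- dplyr::arrange(out, .data$mirna, .data$gene)
  structure(out, source_names = source_names,
            class = c("interaction_tbl", class(tibble())))
}

interaction_sources <- function(t) {
  attr(t, "source_names") %||% setdiff(names(t), c("mirna", "gene", "support"))
}

is_consensus <- function(t) !is.null(attr(t, "consensus_min"))

require_consensus <- function(t, allow_unfiltered = FALSE) {
  if (!is_consensus(t) && !allow_unfiltered) {
    stop_mirlink(
      paste("Interaction table has not been consensus-filtered; run",
            "consensus_filter() first or pass allow_unfiltered = TRUE."),
      "mirlink_consensus_required"
    )
  }
  invisible(t)
}

#' Keep interactions predicted by at least `min_algorithms` sources
#'
#' The consensus filter that suppresses single-algorithm false positives:
#' only pairs flagged by at least `min_algorithms` of the prediction
#' sources are retained (default 2 of 10). Idempotent; filtering at a
#' higher threshold always yields a subset.
#'
#' @param t An `interaction_tbl`.
#' @param min_algorithms Minimum support, >= 1.
#' @return The filtered `interaction_tbl`, carrying a `consensus_min`
#'   attribute consumed by downstream stages.
#' @export
#' @examples
#' t <- as_interactions(tibble::tibble(mirna = "m1", gene = c("g1", "g2"),
#'                                     a = c(1, 1), b = c(1, 0)))
#' nrow(consensus_filter(t, 2))
consensus_filter <- function(t, min_algorithms = 2) {
  min_algorithms <- check_count(min_algorithms, "min_algorithms", 1L)
  stopifnot(inherits(t, "interaction_tbl"))
  out <- t[t$support >= min_algorithms, , drop = FALSE]
  attr(out, "source_names") <- interaction_sources(t)
  attr(out, "consensus_min") <- max(min_algorithms, attr(t, "consensus_min") %||% 1L)
  out
}

#' Union of predicted targets of a set of miRNAs
#'
#' @param t A consensus-filtered `interaction_tbl`.
#' @param mirnas Character vector of miRNA ids; duplicates are ignored.
#' @param allow_unfiltered Permit lookup on an unfiltered table.
#' @return Sorted character vector of target gene ids. Unknown miRNAs
#'   contribute nothing and trigger a warning (expression arrays routinely
#'   contain probes absent from prediction tables).
#' @export
targets_of <- function(t, mirnas, allow_unfiltered = FALSE) {
  require_consensus(t, allow_unfiltered)
  mirnas <- unique(as.character(mirnas))
  unknown <- setdiff(mirnas, unique(t$mirna))
  if (length(unknown)) {
    warn(sprintf("%d miRNA id(s) absent from the interaction table (e.g. %s).",
                 length(unknown), paste(head(unknown, 3L), collapse = ", ")),
         class = "mirlink_unknown_mirna")
  }
  sort(unique(t$gene[t$mirna %in% mirnas]))
}

#' Classify target-hubs and miRNA-hubs
#'
#' A target-hub is a gene predicted by at least `min_hub` distinct miRNAs;
#' a miRNA-hub is a miRNA predicted to target at least `min_hub` distinct
#' genes (default 15, the convention of the underlying study). Degree is
#' the number of distinct partners in the (normally consensus-filtered)
#' table.
#'
#' @param t An `interaction_tbl`, consensus-filtered unless
#'   `allow_unfiltered = TRUE` (provided so pre-filter hub counts can be
#'   compared).
#' @param min_hub Degree threshold, >= 1.
#' @param allow_unfiltered Permit hub counting on an unfiltered table.
#' @return A tibble of class `"hub_report"` with columns `id`, `kind`
#'   (`"target_hub"` / `"mirna_hub"`) and `degree`, sorted by degree
#'   descending then id; `min_hub` is carried as an attribute.
#' @export
find_hubs <- function(t, min_hub = 15, allow_unfiltered = FALSE) {
  require_consensus(t, allow_unfiltered)
  min_hub <- check_count(min_hub, "min_hub", 1L)
  degree_of <- function(key, kind) {
    d <- dplyr::count(tibble(id = key), .data$id, name = "degree")
    d <- d[d$degree >= min_hub, , drop = FALSE]
    d$kind <- kind
    d
  }
  pairs <- dplyr::distinct(tibble(mirna = t$mirna, gene = t$gene))
  out <- dplyr::bind_rows(
    degree_of(pairs$gene, "target_hub"),
    degree_of(pairs$mirna, "mirna_hub")
  )
  out <- out[order(-out$degree, out$id), c("id", "kind", "degree")]
  structure(as_tibble(out), min_hub = min_hub,
            class = c("hub_report", class(tibble())))
}
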