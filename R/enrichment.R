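#' Fisher's exact overrepresentation of one gene set in one query
#'
#' One-sided (upper tail) Fisher's exact test of whether the query list
#' contains more members of the set than expected from the universe:
#' `p = P[X >= k]` with `X ~ Hypergeom(N, K, n)`, where `N` is the universe
#' size, `K` the in-universe set size, `n` the in-universe query size and
#' `k` the overlap. The fold enrichment score is `(k/n) / (K/N)`, i.e. the
#' query concentration of the set relative to its universe frequency.
#'
#' Members of `query` and `geneset` outside the universe are trimmed before
#' testing. An empty query after trimming yields `k = n = 0`, `p = 1` and
#' `NA` fold enrichment rather than an error.
#'
#' @param query,geneset,universe Character vectors of gene ids.
#' @param sided `"greater"` (default, overrepresentation only) or
#'   `"two.sided"` (doubled one-sided tail, capped at 1).
#' @param name Label carried into the result row.
#' @return A one-row tibble: `name`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `fold_enrichment`.
#' @export
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' fisher_overrep(u[1:8], u[1:5], u)  # k = 5, n = 8, K = 5, N = 20
fisher_overrep <- function(query, geneset, universe,
                           sided = c("greater", "two.sided"), name = NA_character_) {
  sided <- match.arg(sided)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop_mirlink("Universe must be nonempty.", "mirlink_invalid_argument")
  }
  query <- intersect(unique(as.character(query)), universe)
  geneset <- intersect(unique(as.character(geneset)), universe)
  N <- length(universe)
  K <- length(geneset)
  n <- length(query)
  k <- length(intersect(query, geneset))
  p <- hyper_upper_tail(k, N, K, n)
  if (sided == "two.sided" && k > 0) {
    p <- min(1, 2 * min(p, 1 - hyper_upper_tail(k + 1, N, K, n)))
  }
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  tibble(name = name, k = k, n = n, K = K, N = N,
         p_raw = p, fold_enrichment = fold)
}

# P[X >= k], X ~ Hypergeom(N, K, n); exact 1 at k <= 0
hyper_upper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

finalize_enrichment <- function(res, alpha, family, query_size, universe = NULL) {
  res <- dplyr::bind_rows(res)
  if (nrow(res)) {
    res$p_adj <- bh_adjust(res$p_raw)
    res$significant <- res$p_adj < alpha & res$k > 0
    res <- res[order(res$p_adj, res$p_raw, res$name), , drop = FALSE]
  } else {
    res <- tibble(name = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), p_raw = numeric(),
                  fold_enrichment = numeric(), p_adj = numeric(),
                  significant = logical())
  }
  structure(as_tibble(res), alpha = alpha, family_size = family,
            query_size = query_size,
            universe_hash = if (!is.null(universe)) rlang::hash(sort(unique(universe))),
            class = c("enrich_result", class(tibble())))
}

#' Pathway overrepresentation of a query gene list
#'
#' Tests every set of a collection against one query via [fisher_overrep()]
#' and BH-adjusts across the whole collection (the tested family). Run it
#' separately on up- and down-regulated lists; each run is its own BH
#' family, matching the separate reporting of the two directions.
#'
#' @param query Character vector of gene ids (e.g. from [de_features()]).
#' @param sets A `gene_sets` collection.
#' @param universe Character vector of gene ids; out-of-universe set
#'   members are trimmed (the trimmed fraction is reported via a message
#'   when nonzero).
#' @param alpha Significance level on BH-adjusted p (default 0.05).
#' @param sided Passed to [fisher_overrep()].
#' @return A tibble of class `"enrich_result"` (`name`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `fold_enrichment`, `p_adj`, `significant`), sorted by
#'   `p_adj`, then `p_raw`, then name. Rows with `k = 0` are retained but
#'   never flagged significant.
#' @export
pathway_enrichment <- function(query, sets, universe, alpha = 0.05,
                               sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(inherits(sets, "gene_sets") || is.data.frame(sets))
  universe <- unique(as.character(universe))
  query_in <- intersect(unique(as.character(query)), universe)
  n_trim <- sum(!unlist(sets$genes) %in% universe)
  if (n_trim > 0) {
    inform(sprintf("%d set member(s) outside the universe were trimmed.", n_trim),
           class = "mirlink_trim_note")
  }
  res <- purrr::map2(sets$genes, sets$set_name, function(g, nm) {
    fisher_overrep(query_in, g, universe, sided = sided, name = nm)
  })
  finalize_enrichment(res, alpha, family = nrow(sets), query_size = length(query_in),
                      universe = universe)
}

#' Binding-site overrepresentation of miRNAs in a DE gene list
#'
#' For every miRNA of a consensus-filtered interaction table with at least
#' one in-universe predicted target, tests whether its target set is
#' overrepresented in the differentially expressed gene list relative to
#' the universe ("all known genes"). BH is applied across all tested
#' miRNAs; run separately for the up- and the down-regulated list, which
#' form separate families. miRNAs with no in-universe target are skipped.
#'
#' @param de_genes Character vector of DE gene ids (one direction).
#' @param t A consensus-filtered `interaction_tbl`.
#' @inheritParams pathway_enrichment
#' @param allow_unfiltered Permit an unfiltered interaction table.
#' @return An `enrich_result` tibble with one row per tested miRNA.
#' @export
mirna_bindingsite_enrichment <- function(de_genes, t, universe, alpha = 0.05,
                                         sided = c("greater", "two.sided"),
                                         allow_unfiltered = FALSE) {
  sided <- match.arg(sided)
  require_consensus(t, allow_unfiltered)
  universe <- unique(as.character(universe))
  de_in <- intersect(unique(as.character(de_genes)), universe)
  targets <- split(t$gene, t$mirna)
  targets <- lapply(targets, function(g) intersect(unique(g), universe))
  skipped <- sum(lengths(targets) == 0L)
  if (skipped > 0) {
    inform(sprintf("%d miRNA(s) with no in-universe target were skipped.", skipped),
           class = "mirlink_trim_note")
  }
  targets <- targets[lengths(targets) > 0L]
  res <- purrr::imap(targets, function(g, nm) {
    fisher_overrep(de_in, g, universe, sided = sided, name = nm)
  })
  finalize_enrichment(res, alpha, family = length(targets), query_size = length(de_in),
                      universe = universe)
}

#' Pathway enrichment of the target union of DE miRNAs
#'
#' The indirect pathway readout of the miRNA layer: the query is the union
#' of consensus-predicted targets of the given miRNAs, interrogated against
#' the pathway collection exactly as a DE gene list would be. Run
#' separately for up- and down-regulated miRNA sets.
#'
#' @param de_mirnas Character vector of miRNA ids (one direction);
#'   duplicates are ignored.
#' @param t A consensus-filtered `interaction_tbl`.
#' @inheritParams pathway_enrichment
#' @param allow_unfiltered Permit an unfiltered interaction table.
#' @return An `enrich_result`; the target-union query size is recorded in
#'   the `query_size` attribute.
#' @export
mirna_pathway_enrichment <- function(de_mirnas, t, sets, universe, alpha = 0.05,
                                     sided = c("greater", "two.sided"),
                                     allow_unfiltered = FALSE) {
  sided <- match.arg(sided)
  require_consensus(t, allow_unfiltered)
  query <- if (length(de_mirnas)) targets_of(t, de_mirnas, allow_unfiltered = TRUE)
           else character()
  pathway_enrichment(query, sets, universe, alpha = alpha, sided = sided)
}

#' Names of significant sets in an enrichment result
#'
#' @param res An `enrich_result`.
#' @return Sorted character vector of significant names.
#' @export
significant_names <- function(res) {
  stopifnot(is.data.frame(res), all(c("name", "significant") %in% names(res)))
  sort(res$name[res$significant])
}
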