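#' Inverse-expression intersection of DE genes and DE miRNA targets
#'
#' The integration step linking the two expression layers under the
#' assumption of negative regulation: up-regulated genes that are
#' consensus-predicted targets of down-regulated miRNAs, and vice versa.
#' Besides the two gene sets, the full list of supporting (miRNA, gene)
#' pairs is returned — every reported count is the cardinality of a set
#' that is also emitted.
#'
#' @param up_genes,down_genes Character vectors of declared DE gene ids.
#' @param up_mirnas,down_mirnas Character vectors of declared DE miRNA ids.
#' @param t A consensus-filtered `interaction_tbl`.
#' @param allow_unfiltered Permit an unfiltered table (for comparing the
#'   raw prediction union with the consensus).
#' @return A list of class `"inverse_intersection"`:
#'   `up_gene_down_mirna` / `down_gene_up_mirna` (sorted gene sets) and
#'   `pairs`, a tibble (`mirna`, `gene`, `pairing`) of supporting pairs.
#' @export
inverse_intersection <- function(up_genes, down_genes, up_mirnas, down_mirnas,
                                 t, allow_unfiltered = FALSE) {
  require_consensus(t, allow_unfiltered)
  one_side <- function(genes, mirnas, pairing) {
    hits <- t[t$mirna %in% mirnas & t$gene %in% genes, c("mirna", "gene")]
    hits$pairing <- pairing
    hits
  }
  p1 <- one_side(unique(up_genes), unique(down_mirnas), "up_gene_down_mirna")
  p2 <- one_side(unique(down_genes), unique(up_mirnas), "down_gene_up_mirna")
  pairs <- dplyr::arrange(as_tibble(dplyr::bind_rows(p1, p2)),
                          .data$pairing, .data$mirna, .data$gene)
  structure(
    list(
      up_gene_down_mirna = sort(unique(p1$gene)),
      down_gene_up_mirna = sort(unique(p2$gene)),
      pairs = pairs
    ),
    class = "inverse_intersection"
  )
}

#' Pathways found by both the gene-based and the miRNA-target-based route
#'
#' Intersects the significant pathway names of the gene-list enrichment
#' with those of the miRNA-target enrichment, paired by inverse direction:
#' up-genes with down-miRNAs and down-genes with up-miRNAs (a same-direction
#' mode exists for diagnostics only).
#'
#' @param gene_up,gene_down Significant pathway names from the up-/down-
#'   gene enrichment (vectors or `enrich_result`s).
#' @param mirna_up,mirna_down Same, from the up-/down-miRNA target
#'   enrichment.
#' @param pairing `"inverse"` (default) or `"same"`.
#' @return A list with sorted name vectors `up_gene_down_mirna` and
#'   `down_gene_up_mirna` (or `up_up` / `down_down` under `"same"`).
#' @export
overlap_pathways <- function(gene_up, gene_down, mirna_up, mirna_down,
                             pairing = c("inverse", "same")) {
  pairing <- match.arg(pairing)
  as_names <- function(x) {
    if (is.data.frame(x)) significant_names(x) else sort(unique(as.character(x)))
  }
  gene_up <- as_names(gene_up); gene_down <- as_names(gene_down)
  mirna_up <- as_names(mirna_up); mirna_down <- as_names(mirna_down)
  if (pairing == "inverse") {
    list(
      up_gene_down_mirna = sort(intersect(gene_up, mirna_down)),
      down_gene_up_mirna = sort(intersect(gene_down, mirna_up))
    )
  } else {
    list(
      up_up = sort(intersect(gene_up, mirna_up)),
      down_down = sort(intersect(gene_down, mirna_down))
    )
  }
}

#' DE miRNAs that are also binding-site-enriched in the opposite gene list
#'
#' Under negative regulation, a down-regulated miRNA should show
#' binding-site enrichment among up-regulated genes (and vice versa); this
#' intersects the declared DE miRNA sets with the significant miRNAs of
#' the opposite-direction binding-site enrichment.
#'
#' @param up_mirnas,down_mirnas Declared DE miRNA ids.
#' @param enriched_in_up,enriched_in_down Significant miRNA names from
#'   [mirna_bindingsite_enrichment()] on the up-/down-gene lists (vectors
#'   or `enrich_result`s).
#' @return A list with sorted vectors `down_mirnas_enriched_in_up_genes`
#'   and `up_mirnas_enriched_in_down_genes`.
#' @export
enriched_mirna_overlap <- function(up_mirnas, down_mirnas,
                                   enriched_in_up, enriched_in_down) {
  as_names <- function(x) {
    if (is.data.frame(x)) significant_names(x) else sort(unique(as.character(x)))
  }
  list(
    down_mirnas_enriched_in_up_genes =
      sort(intersect(unique(down_mirnas), as_names(enriched_in_up))),
    up_mirnas_enriched_in_down_genes =
      sort(intersect(unique(up_mirnas), as_names(enriched_in_down)))
  )
}

#' Assemble the three-block integration summary
#'
#' Collects the whole pipeline into the summary layout of the source
#' study: an mRNA block (declared genes and significant pathways per
#' direction, binding-site-enriched miRNAs), a miRNA block (declared
#' miRNAs, target-based pathways), and a common block (inverse-expression
#' gene intersections, overlapping pathways, DE miRNAs enriched in the
#' opposite gene list). Every count is the cardinality of a set carried in
#' `$sets`; the configuration fingerprint is embedded so summaries from
#' mismatched runs cannot be confused.
#'
#' @param gene_de,mirna_de Classified `de_result`s for the two layers.
#' @param gene_enrich_up,gene_enrich_down `enrich_result`s of the DE gene
#'   lists against pathways.
#' @param mirna_enrich_up,mirna_enrich_down `enrich_result`s of the DE
#'   miRNA target unions against pathways.
#' @param bindingsite_up,bindingsite_down `enrich_result`s of
#'   [mirna_bindingsite_enrichment()] on the up-/down-gene lists.
#' @param inverse An [inverse_intersection()] result.
#' @param config The [analysis_config()] of the run.
#' @return A list of class `"integration_summary"` with elements `counts`
#'   (tibble: `block`, `quantity`, `up`, `down`), `sets` (the underlying
#'   id sets), `pairs` and `fingerprint`.
#' @export
build_summary <- function(gene_de, mirna_de,
                          gene_enrich_up, gene_enrich_down,
                          mirna_enrich_up, mirna_enrich_down,
                          bindingsite_up, bindingsite_down,
                          inverse, config = analysis_config()) {
  stopifnot(inherits(inverse, "inverse_intersection"))
  hashes <- purrr::compact(purrr::map(
    list(gene_enrich_up, gene_enrich_down, mirna_enrich_up, mirna_enrich_down,
         bindingsite_up, bindingsite_down),
    attr, "universe_hash"
  ))
  if (length(unique(unlist(hashes))) > 1L) {
    stop_mirlink(
      "Enrichment stages were run against different universes; refusing to combine.",
      "mirlink_consistency_error"
    )
  }
  sets <- list(
    up_genes = de_features(gene_de, "up"),
    down_genes = de_features(gene_de, "down"),
    up_mirnas = de_features(mirna_de, "up"),
    down_mirnas = de_features(mirna_de, "down"),
    gene_pathways_up = significant_names(gene_enrich_up),
    gene_pathways_down = significant_names(gene_enrich_down),
    mirna_pathways_up = significant_names(mirna_enrich_up),
    mirna_pathways_down = significant_names(mirna_enrich_down),
    bindingsite_enriched_in_up = significant_names(bindingsite_up),
    bindingsite_enriched_in_down = significant_names(bindingsite_down)
  )
  ov <- overlap_pathways(sets$gene_pathways_up, sets$gene_pathways_down,
                         sets$mirna_pathways_up, sets$mirna_pathways_down)
  em <- enriched_mirna_overlap(sets$up_mirnas, sets$down_mirnas,
                               sets$bindingsite_enriched_in_up,
                               sets$bindingsite_enriched_in_down)
  sets$inverse_up_gene_down_mirna <- inverse$up_gene_down_mirna
  sets$inverse_down_gene_up_mirna <- inverse$down_gene_up_mirna
  sets$overlap_pathways_up <- ov$up_gene_down_mirna
  sets$overlap_pathways_down <- ov$down_gene_up_mirna
  sets$enriched_mirnas_overlap_up <- em$down_mirnas_enriched_in_up_genes
  sets$enriched_mirnas_overlap_down <- em$up_mirnas_enriched_in_down_genes

  counts <- tibble(
    block = rep(c("mRNA", "miRNA", "common"), c(3L, 2L, 3L)),
    quantity = c("genes", "pathways", "enriched_putative_mirnas",
                 "mirnas", "pathways",
                 "genes", "pathways", "enriched_mirnas"),
    up = c(length(sets$up_genes), length(sets$gene_pathways_up),
           length(sets$bindingsite_enriched_in_up),
           length(sets$up_mirnas), length(sets$mirna_pathways_up),
           length(sets$inverse_up_gene_down_mirna),
           length(sets$overlap_pathways_up),
           length(sets$enriched_mirnas_overlap_up)),
    down = c(length(sets$down_genes), length(sets$gene_pathways_down),
             length(sets$bindingsite_enriched_in_down),
             length(sets$down_mirnas), length(sets$mirna_pathways_down),
             length(sets$inverse_down_gene_up_mirna),
             length(sets$overlap_pathways_down),
             length(sets$enriched_mirnas_overlap_down))
  )
  structure(
    list(counts = counts, sets = sets, pairs = inverse$pairs,
         fingerprint = config_fingerprint(config)),
    class = "integration_summary"
  )
}

#' @export
print.integration_summary <- function(x, ...) {
  cat("<integration_summary> config", x$fingerprint, "\n")
  df <- as.data.frame(x$counts)
  for (b in unique(df$block)) {
    cat(sprintf("-- %s --\n", b))
    sub <- df[df$block == b, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-26s up %6d   down %6d\n", sub$quantity[i], sub$up[i], sub$down[i]))
    }
  }
  invisible(x)
}
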