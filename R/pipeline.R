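#' Run the full integrative analysis end to end
#'
#' The `all` driver: starting from a simulation bundle (or any list with
#' the same elements, e.g. from [read_fixture()]), it quantile-normalizes
#' both layers, tests every feature, declares the DE sets, consensus-filters
#' the interaction table, finds hubs, runs the three enrichment analyses
#' (pathways on DE genes, binding sites on DE genes, pathways on DE miRNA
#' targets — up and down separately throughout), computes the
#' inverse-expression intersection and assembles the integration summary.
#'
#' @param data A `mirlink_sim` bundle or a list with elements `genes`,
#'   `mirnas`, `design`, `interactions`, `gene_sets`, `universe` (and
#'   optionally `truth`). If `NULL`, a dataset is simulated from
#'   `sim_params(seed = config$seed)`.
#' @param config An [analysis_config()].
#' @param out_dir If non-`NULL`, every stage artifact is written there as
#'   TSV/GMT plus a `manifest.tsv` with an MD5 checksum per file; the run
#'   is byte-reproducible given the same data and config.
#' @param normalize Quantile-normalize the two layers first (default TRUE).
#' @return A list of class `"mirlink_run"` with elements `gene_de`,
#'   `mirna_de`, `hubs`, `interactions` (consensus-filtered),
#'   `gene_enrich`, `mirna_enrich`, `bindingsite` (each `$up`/`$down`),
#'   `inverse`, `summary`, `config`, and `manifest` (or `NULL`).
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(simulate_dataset(sim_params(n_genes = 300, n_mirnas = 30,
#'                                                 seed = 2)),
#'                     analysis_config(seed = 2))
#' run$summary$counts
#' }
run_pipeline <- function(data = NULL, config = analysis_config(),
                         out_dir = NULL, normalize = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(data)) data <- simulate_dataset(sim_params(seed = config$seed))
  needed <- c("genes", "mirnas", "design", "interactions", "gene_sets", "universe")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop_mirlink(sprintf("Input bundle lacks element(s): %s",
                         paste(missing, collapse = ", ")),
                 "mirlink_schema_error")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mirlink(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
                   "mirlink_stage_error", parent = e)
    })
  }

  genes <- stage("normalize", {
    g <- log2_if_linear(data$genes)
    if (normalize) quantile_normalize(g) else g
  })
  mirnas <- stage("normalize", {
    m <- log2_if_linear(data$mirnas)
    if (normalize) quantile_normalize(m) else m
  })

  gene_de <- stage("de_genes",
                   classify_de(de_anova(genes, data$design), config$gene_filter))
  mirna_de <- stage("de_mirnas",
                    classify_de(de_anova(mirnas, data$design), config$mirna_filter))

  cons <- stage("targets", consensus_filter(data$interactions, config$min_algorithms))
  hubs <- stage("targets", find_hubs(cons, config$min_hub))

  universe <- switch(config$universe_mode,
    annotation = unique(as.character(data$universe)),
    measured = as.character(genes[[1L]])
  )
  up_g <- de_features(gene_de, "up"); down_g <- de_features(gene_de, "down")
  up_m <- de_features(mirna_de, "up"); down_m <- de_features(mirna_de, "down")

  al <- config$alpha_enrichment; sd_ <- config$sided
  gene_enrich <- stage("enrich", list(
    up = pathway_enrichment(up_g, data$gene_sets, universe, al, sd_),
    down = pathway_enrichment(down_g, data$gene_sets, universe, al, sd_)
  ))
  bindingsite <- stage("enrich", list(
    up = mirna_bindingsite_enrichment(up_g, cons, universe, al, sd_),
    down = mirna_bindingsite_enrichment(down_g, cons, universe, al, sd_)
  ))
  mirna_enrich <- stage("enrich", list(
    up = mirna_pathway_enrichment(up_m, cons, data$gene_sets, universe, al, sd_),
    down = mirna_pathway_enrichment(down_m, cons, data$gene_sets, universe, al, sd_)
  ))

  inverse <- stage("integrate",
                   inverse_intersection(up_g, down_g, up_m, down_m, cons))
  summary <- stage("integrate", build_summary(
    gene_de, mirna_de, gene_enrich$up, gene_enrich$down,
    mirna_enrich$up, mirna_enrich$down, bindingsite$up, bindingsite$down,
    inverse, config
  ))

  run <- structure(
    list(gene_de = gene_de, mirna_de = mirna_de, hubs = hubs,
         interactions = cons, gene_enrich = gene_enrich,
         mirna_enrich = mirna_enrich, bindingsite = bindingsite,
         inverse = inverse, summary = summary, config = config,
         manifest = NULL),
    class = "mirlink_run"
  )
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

# write every stage artifact plus a checksum manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- config_fingerprint(run$config)
  meta <- list(config = fp, seed = run$config$seed)
  f <- function(name) file.path(out_dir, name)
  paths <- c(
    gene_de = write_tsv_meta(as_tibble(run$gene_de), f("gene_de.tsv"), meta),
    mirna_de = write_tsv_meta(as_tibble(run$mirna_de), f("mirna_de.tsv"), meta),
    up_genes = write_id_list(de_features(run$gene_de, "up"), f("up_genes.txt"), meta),
    down_genes = write_id_list(de_features(run$gene_de, "down"), f("down_genes.txt"), meta),
    up_mirnas = write_id_list(de_features(run$mirna_de, "up"), f("up_mirnas.txt"), meta),
    down_mirnas = write_id_list(de_features(run$mirna_de, "down"), f("down_mirnas.txt"), meta),
    hubs = write_tsv_meta(as_tibble(run$hubs), f("hubs.tsv"), meta),
    gene_enrich_up = write_enrichment(run$gene_enrich$up, f("gene_enrich_up.tsv"), meta),
    gene_enrich_down = write_enrichment(run$gene_enrich$down, f("gene_enrich_down.tsv"), meta),
    mirna_enrich_up = write_enrichment(run$mirna_enrich$up, f("mirna_enrich_up.tsv"), meta),
    mirna_enrich_down = write_enrichment(run$mirna_enrich$down, f("mirna_enrich_down.tsv"), meta),
    bindingsite_up = write_enrichment(run$bindingsite$up, f("bindingsite_up.tsv"), meta),
    bindingsite_down = write_enrichment(run$bindingsite$down, f("bindingsite_down.tsv"), meta),
    inverse_pairs = write_tsv_meta(run$inverse$pairs, f("inverse_pairs.tsv"), meta),
    summary = write_tsv_meta(run$summary$counts, f("summary.tsv"),
                             c(meta, list(blocks = "mRNA|miRNA|common")))
  )
  manifest <- tibble(
    artifact = names(paths),
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  readr::write_tsv(manifest, f("manifest.tsv"))
  manifest
}

#' @export
print.mirlink_run <- function(x, ...) {
  cat("<mirlink_run>\n")
  print(x$summary)
  invisible(x)
}
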