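#' Simulation parameters for the synthetic two-layer dataset
#'
#' Bundles and validates every knob of [simulate_dataset()]. Defaults describe
#' the study design the simulator emulates: a two-group (young vs adult)
#' microarray comparison with 4 arrays per group, log-normal intensity noise,
#' a subset of differentially expressed miRNAs whose regulons are pushed in
#' the opposite direction (negative regulation), a set of independently
#' differentially expressed genes, ten noisy target-prediction sources, and
#' pathway gene sets enriched for the planted DE genes.
#'
#' All expression effects are in log2 units. A planted DE miRNA receives a
#' group shift of `+/- mirna_effect` (adult minus young); each gene in its
#' regulon receives `-coupling_beta` times the regulator's shift, so positive
#' `coupling_beta` yields the inverse expression coupling expected of miRNA
#' repression. Each prediction source flags a true miRNA-gene pair with
#' probability `source_tpr` and any other pair with probability `source_fpr`.
#'
#' @param n_genes,n_mirnas Number of gene / miRNA features.
#' @param n_young,n_adult Samples per group (each must be >= 2).
#' @param frac_de_mirnas Fraction of miRNAs given a planted group shift.
#' @param mirna_effect Absolute log2 group shift of a planted DE miRNA.
#' @param regulon_size Number of target genes per planted DE miRNA.
#' @param coupling_beta Negative-regulation strength: a regulon gene's shift
#'   is `-coupling_beta * regulator_shift` (summed over regulators).
#' @param indep_gene_effect Absolute log2 shift of independently DE genes.
#' @param frac_de_genes_indep Fraction of genes independently DE.
#' @param noise_sd Residual standard deviation (log2 units), must be > 0.
#' @param baseline_mean,baseline_sd Mean and s.d. of per-feature baseline
#'   log2 intensity.
#' @param n_sources Number of prediction algorithms (>= 2).
#' @param source_tpr,source_fpr Per-source probability that a true / false
#'   pair is flagged.
#' @param n_pathways Number of synthetic gene sets.
#' @param pathway_size_range Length-2 integer range of set sizes.
#' @param pathway_de_bias Sampling-weight multiplier applied to expected-DE
#'   genes when drawing pathway members (1 = no enrichment).
#' @param overlapping_regulons If `TRUE`, regulons are drawn independently
#'   with replacement across miRNAs and shifts add; default keeps them
#'   disjoint so expected directions are unambiguous.
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the seed.
#'
#' @return A validated list of class `"sim_params"`.
#' @seealso [simulate_dataset()], [generate_design()]
#' @export
#' @examples
#' p <- sim_params(n_genes = 200, n_mirnas = 20, seed = 1)
#' p$regulon_size
sim_params <- function(n_genes = 2000,
                       n_mirnas = 200,
                       n_young = 4,
                       n_adult = 4,
                       frac_de_mirnas = 0.1,
                       mirna_effect = 1.5,
                       regulon_size = 20,
                       coupling_beta = 1,
                       indep_gene_effect = 1,
                       frac_de_genes_indep = 0.05,
                       noise_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       n_sources = 10,
                       source_tpr = 0.8,
                       source_fpr = 0.01,
                       n_pathways = 50,
                       pathway_size_range = c(20, 100),
                       pathway_de_bias = 5,
                       overlapping_regulons = FALSE,
                       seed = 1L) {
  p <- list(
    n_genes = check_count(n_genes, "n_genes", 1L),
    n_mirnas = check_count(n_mirnas, "n_mirnas", 1L),
    n_young = check_count(n_young, "n_young", 2L),
    n_adult = check_count(n_adult, "n_adult", 2L),
    frac_de_mirnas = check_fraction(frac_de_mirnas, "frac_de_mirnas"),
    mirna_effect = check_number(mirna_effect, "mirna_effect", 0),
    regulon_size = check_count(regulon_size, "regulon_size", 0L),
    coupling_beta = check_number(coupling_beta, "coupling_beta"),
    indep_gene_effect = check_number(indep_gene_effect, "indep_gene_effect", 0),
    frac_de_genes_indep = check_fraction(frac_de_genes_indep, "frac_de_genes_indep"),
    noise_sd = check_number(noise_sd, "noise_sd", 0, strict = TRUE),
    baseline_mean = check_number(baseline_mean, "baseline_mean"),
    baseline_sd = check_number(baseline_sd, "baseline_sd", 0),
    n_sources = check_count(n_sources, "n_sources", 2L),
    source_tpr = check_fraction(source_tpr, "source_tpr"),
    source_fpr = check_fraction(source_fpr, "source_fpr"),
    n_pathways = check_count(n_pathways, "n_pathways", 0L),
    pathway_size_range = pathway_size_range,
    pathway_de_bias = check_number(pathway_de_bias, "pathway_de_bias", 0, strict = TRUE),
    overlapping_regulons = isTRUE(overlapping_regulons),
    seed = check_count(seed, "seed", 0L)
  )
  if (length(p$pathway_size_range) != 2L || any(p$pathway_size_range < 1) ||
      p$pathway_size_range[1] > p$pathway_size_range[2]) {
    stop_mirlink("`pathway_size_range` must be an increasing pair of counts >= 1.",
                 "mirlink_invalid_argument")
  }
  if (p$pathway_size_range[2] > p$n_genes) {
    stop_mirlink("`pathway_size_range` exceeds the number of genes.",
                 "mirlink_config_error")
  }
  n_de_mirnas <- round(p$frac_de_mirnas * p$n_mirnas)
  if (!p$overlapping_regulons && p$regulon_size * n_de_mirnas > p$n_genes) {
    stop_mirlink(
      sprintf(paste0("Infeasible regulon allocation: %d DE miRNAs x regulon_size %d ",
                     "exceeds %d genes (disjoint regulons)."),
              n_de_mirnas, p$regulon_size, p$n_genes),
      "mirlink_config_error"
    )
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) cat(" ", nm, "=", paste(format(x[[nm]]), collapse = ", "), "\n")
  invisible(x)
}

#' Differential-expression filter specification
#'
#' Encodes the thresholds that turn per-feature statistics into declared
#' up/down sets. The `"gene"` default requires BH-adjusted p < 0.01 and a
#' nonzero log2 fold change; the `"mirna"` default additionally requires a
#' 1.5-fold change and applies p < 0.001 to the raw p-value (set
#' `use_adjusted = TRUE` to apply it to the adjusted one). The `"recovery"`
#' preset (raw p < 0.05, any fold change) is the per-feature sensitivity
#' criterion used when scoring simulations against ground truth, where the
#' question is whether a planted signal is individually detectable with the
#' correct sign rather than whether it survives a stringent list filter.
#'
#' @param kind One of `"gene"`, `"mirna"`, `"recovery"`, or `"custom"`.
#' @param p_threshold Significance threshold in (0, 1].
#' @param use_adjusted Apply `p_threshold` to BH-adjusted p-values?
#' @param fc_threshold Linear-scale fold-change threshold, >= 1; a feature
#'   must satisfy `abs(log2fc) >= log2(fc_threshold)`.
#'
#' @return A list of class `"filter_spec"`.
#' @export
#' @examples
#' filter_spec("gene")
#' filter_spec("mirna", use_adjusted = TRUE)
filter_spec <- function(kind = c("gene", "mirna", "recovery", "custom"),
                        p_threshold = NULL,
                        use_adjusted = NULL,
                        fc_threshold = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    gene = list(p_threshold = 0.01, use_adjusted = TRUE, fc_threshold = 1),
    mirna = list(p_threshold = 0.001, use_adjusted = FALSE, fc_threshold = 1.5),
    recovery = list(p_threshold = 0.05, use_adjusted = FALSE, fc_threshold = 1),
    custom = list(p_threshold = 0.05, use_adjusted = TRUE, fc_threshold = 1)
  )
  spec <- list(
    kind = kind,
    p_threshold = check_number(p_threshold %||% defaults$p_threshold,
                               "p_threshold", 0, strict = TRUE),
    use_adjusted = isTRUE(use_adjusted %||% defaults$use_adjusted),
    fc_threshold = check_number(fc_threshold %||% defaults$fc_threshold, "fc_threshold", 1)
  )
  if (spec$p_threshold > 1) {
    stop_mirlink("`p_threshold` must lie in (0, 1].", "mirlink_invalid_argument")
  }
  structure(spec, class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec: %s> p %s %.4g, fold change >= %.3g\n",
              x$kind, if (x$use_adjusted) "(BH-adjusted) <" else "(raw) <",
              x$p_threshold, x$fc_threshold))
  invisible(x)
}

#' Pipeline-wide analysis configuration
#'
#' Collects every threshold the end-to-end pipeline uses so a run is fully
#' described (and fingerprinted) by one object. Defaults mirror the
#' published criteria: genes declared DE at BH-adjusted p < 0.01, miRNAs at
#' 1.5-fold with raw p < 0.001, target consensus at >= 2 of the prediction
#' algorithms, hubs at >= 15 partners, and enrichment at BH-adjusted
#' p < 0.05 with a one-sided (overrepresentation) Fisher test.
#'
#' @param gene_filter,mirna_filter [filter_spec()] objects for the two layers.
#' @param min_algorithms Consensus threshold on prediction-source support.
#' @param min_hub Degree threshold for target-/miRNA-hubs.
#' @param alpha_enrichment Significance level applied to BH-adjusted
#'   enrichment p-values.
#' @param sided `"greater"` (overrepresentation, default) or `"two.sided"`.
#' @param universe_mode `"annotation"` (the collection's universe file,
#'   default) or `"measured"` (genes on the array).
#' @param seed Integer seed forwarded to simulation when the pipeline
#'   generates its own input.
#'
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(gene_filter = filter_spec("gene"),
                            mirna_filter = filter_spec("mirna"),
                            min_algorithms = 2,
                            min_hub = 15,
                            alpha_enrichment = 0.05,
                            sided = c("greater", "two.sided"),
                            universe_mode = c("annotation", "measured"),
                            seed = 1L) {
  stopifnot(inherits(gene_filter, "filter_spec"), inherits(mirna_filter, "filter_spec"))
  cfg <- list(
    gene_filter = gene_filter,
    mirna_filter = mirna_filter,
    min_algorithms = check_count(min_algorithms, "min_algorithms", 1L),
    min_hub = check_count(min_hub, "min_hub", 1L),
    alpha_enrichment = check_number(alpha_enrichment, "alpha_enrichment", 0, strict = TRUE),
    sided = match.arg(sided),
    universe_mode = match.arg(universe_mode),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$alpha_enrichment > 1) {
    stop_mirlink("`alpha_enrichment` must lie in (0, 1].", "mirlink_invalid_argument")
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>", "fingerprint:", config_fingerprint(x), "\n")
  cat("  gene filter:  "); print(x$gene_filter)
  cat("  miRNA filter: "); print(x$mirna_filter)
  cat(sprintf("  consensus >= %d sources; hubs >= %d partners; enrichment alpha %.3g (%s)\n",
              x$min_algorithms, x$min_hub, x$alpha_enrichment, x$sided))
  invisible(x)
}
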