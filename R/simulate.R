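#' Simulate a coupled two-group mRNA/miRNA study with known ground truth
#'
#' Generates, from a single seed, everything the pipeline consumes: log2
#' expression tables for genes and miRNAs under a young/adult design, a
#' multi-source miRNA-target interaction table, a pathway gene-set
#' collection, the gene universe, and the planted ground truth.
#'
#' The generative model works on the log2 scale. Each feature draws a
#' baseline intensity `N(baseline_mean, baseline_sd)`. A fraction
#' `frac_de_mirnas` of miRNAs receives a group shift of `+/- mirna_effect`
#' in adult samples; every gene in a DE miRNA's regulon receives
#' `-coupling_beta` times its regulator's shift (negative regulation), and
#' an independent fraction of genes receives `+/- indep_gene_effect`. A gene
#' hit by several effects receives their sum. i.i.d. `N(0, noise_sd)` noise
#' is added per cell. Each of `n_sources` prediction algorithms flags a true
#' (regulon) pair with probability `source_tpr` and any other miRNA-gene
#' pair with probability `source_fpr`; only pairs flagged at least once are
#' stored. Pathway sets oversample expected-DE genes by the factor
#' `pathway_de_bias`.
#'
#' The RNG stream is consumed in a fixed, documented order (miRNA effects,
#' gene effects, expression noise, prediction sources, pathways), so two
#' calls with identical parameters are bit-identical.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `"mirlink_sim"` with elements `genes`, `mirnas`
#'   (log2 expression tibbles), `design`, `interactions`, `gene_sets`,
#'   `universe` (character vector), `truth` (see Details) and `params`.
#'   `truth` holds `de_mirnas` (miRNA, direction, shift), `regulons`
#'   (miRNA-gene pairs, equal to the true interaction set),
#'   `de_genes_expected` (gene, direction, total shift; zero-sum genes are
#'   excluded) and `n_*` convenience counts.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(n_genes = 300, n_mirnas = 30, seed = 7))
#' sim$truth$de_mirnas
simulate_dataset <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) {
    stop_mirlink("`params` must come from sim_params().", "mirlink_invalid_argument")
  }
  p <- params
  set.seed(p$seed)

  gene_ids <- sprintf("gene_%04d", seq_len(p$n_genes))
  mirna_ids <- sprintf("mir_%03d", seq_len(p$n_mirnas))
  design <- generate_design(p$n_young, p$n_adult)

  ## 1. miRNA effects -------------------------------------------------------
  n_de_mir <- round(p$frac_de_mirnas * p$n_mirnas)
  de_mirnas <- sort(sample(mirna_ids, n_de_mir))
  mir_sign <- sample(c(-1, 1), n_de_mir, replace = TRUE)
  mir_shift <- setNames(rep(0, p$n_mirnas), mirna_ids)
  mir_shift[de_mirnas] <- mir_sign * p$mirna_effect

  ## 2. gene effects: regulons, then independent DE -------------------------
  if (n_de_mir > 0 && p$regulon_size > 0) {
    if (p$overlapping_regulons) {
      regulon_genes <- unlist(lapply(seq_len(n_de_mir), function(i) {
        sample(gene_ids, p$regulon_size)
      }))
    } else {
      regulon_genes <- sample(gene_ids, n_de_mir * p$regulon_size)
    }
    regulons <- tibble(
      mirna = rep(de_mirnas, each = p$regulon_size),
      gene = regulon_genes
    )
  } else {
    regulons <- tibble(mirna = character(), gene = character())
  }
  gene_shift <- setNames(rep(0, p$n_genes), gene_ids)
  if (nrow(regulons)) {
    contrib <- -p$coupling_beta * mir_shift[regulons$mirna]
    shift_by_gene <- tapply(contrib, regulons$gene, sum)
    gene_shift[names(shift_by_gene)] <- gene_shift[names(shift_by_gene)] + shift_by_gene
  }
  n_indep <- round(p$frac_de_genes_indep * p$n_genes)
  indep_genes <- if (n_indep > 0) sort(sample(gene_ids, n_indep)) else character()
  if (n_indep > 0) {
    indep_sign <- sample(c(-1, 1), n_indep, replace = TRUE)
    gene_shift[indep_genes] <- gene_shift[indep_genes] + indep_sign * p$indep_gene_effect
  }

  ## 3. expression noise ----------------------------------------------------
  n_samples <- nrow(design)
  adult <- as.numeric(design$group == "adult")
  mir_base <- rnorm(p$n_mirnas, p$baseline_mean, p$baseline_sd)
  gene_base <- rnorm(p$n_genes, p$baseline_mean, p$baseline_sd)
  mir_mat <- mir_base + outer(mir_shift, adult) +
    matrix(rnorm(p$n_mirnas * n_samples, 0, p$noise_sd), p$n_mirnas)
  gene_mat <- gene_base + outer(gene_shift, adult) +
    matrix(rnorm(p$n_genes * n_samples, 0, p$noise_sd), p$n_genes)
  colnames(mir_mat) <- colnames(gene_mat) <- design$sample_id
  rownames(mir_mat) <- mirna_ids
  rownames(gene_mat) <- gene_ids

  ## 4. prediction sources --------------------------------------------------
  interactions <- simulate_interactions(mirna_ids, gene_ids, regulons, p)

  ## 5. pathways ------------------------------------------------------------
  expected_de <- gene_ids[gene_shift != 0]
  gene_sets <- simulate_gene_sets(gene_ids, expected_de, p)

  truth <- list(
    de_mirnas = tibble(
      mirna = de_mirnas,
      direction = ifelse(mir_sign > 0, "up", "down"),
      shift = mir_sign * p$mirna_effect
    ),
    regulons = dplyr::arrange(regulons, .data$mirna, .data$gene),
    de_genes_expected = tibble(
      gene = expected_de,
      direction = ifelse(gene_shift[expected_de] > 0, "up", "down"),
      shift = unname(gene_shift[expected_de])
    ),
    n_de_mirnas = n_de_mir,
    n_true_interactions = nrow(regulons)
  )
  truth$true_interactions <- truth$regulons

  structure(
    list(
      genes = as_expression(matrix_to_expr(gene_mat, "feature_id"), "log2"),
      mirnas = as_expression(matrix_to_expr(mir_mat, "feature_id"), "log2"),
      design = design,
      interactions = interactions,
      gene_sets = gene_sets,
      universe = gene_ids,
      truth = truth,
      params = p
    ),
    class = "mirlink_sim"
  )
}

# Per-source Bernoulli flags. True pairs draw a full flag matrix (their
# per-source marginals are a tested property); false pairs draw a binomial
# support count first and then the identity of the flagging sources, which
# avoids materialising the full n_mirnas x n_genes x n_sources array.
simulate_interactions <- function(mirna_ids, gene_ids, regulons, p) {
  n_mir <- length(mirna_ids)
  n_gene <- length(gene_ids)
  src_names <- sprintf("src_%02d", seq_len(p$n_sources))

  pair_index <- function(mirna, gene) {
    (match(mirna, mirna_ids) - 1L) * n_gene + match(gene, gene_ids)
  }
  true_idx <- if (nrow(regulons)) sort(pair_index(regulons$mirna, regulons$gene)) else integer()

  # true pairs
  n_true <- length(true_idx)
  true_flags <- matrix(rbinom(n_true * p$n_sources, 1L, p$source_tpr), nrow = n_true)

  # false pairs: support counts, then source identities for the hits
  n_false <- n_mir * n_gene - n_true
  false_support <- rbinom(n_false, p$n_sources, p$source_fpr)
  hit <- which(false_support > 0L)
  false_idx_all <- setdiff(seq_len(n_mir * n_gene), true_idx)
  hit_idx <- false_idx_all[hit]
  hit_support <- false_support[hit]
  false_flags <- matrix(0L, length(hit), p$n_sources)
  for (i in seq_along(hit)) {
    false_flags[i, sample.int(p$n_sources, hit_support[i])] <- 1L
  }

  all_idx <- c(true_idx, hit_idx)
  all_flags <- rbind(true_flags, false_flags)
  keep <- rowSums(all_flags) > 0L
  all_idx <- all_idx[keep]
  all_flags <- all_flags[keep, , drop = FALSE]
  ord <- order(all_idx)
  all_idx <- all_idx[ord]
  all_flags <- all_flags[ord, , drop = FALSE]

  flags <- as_tibble(as.data.frame(all_flags))
  names(flags) <- src_names
  out <- tibble(
    mirna = mirna_ids[(all_idx - 1L) %/% n_gene + 1L],
    gene = gene_ids[(all_idx - 1L) %% n_gene + 1L]
  )
  out <- dplyr::bind_cols(out, flags)
  out$support <- as.integer(rowSums(all_flags))
  as_interactions(out, source_names = src_names)
}

simulate_gene_sets <- function(gene_ids, expected_de, p) {
  if (p$n_pathways == 0L) {
    return(new_gene_sets(tibble(set_name = character(), description = character(),
                                genes = list())))
  }
  sizes <- sample(seq(p$pathway_size_range[1], p$pathway_size_range[2]),
                  p$n_pathways, replace = TRUE)
  weights <- ifelse(gene_ids %in% expected_de, p$pathway_de_bias, 1)
  sets <- lapply(sizes, function(k) sort(sample(gene_ids, k, prob = weights)))
  new_gene_sets(tibble(
    set_name = sprintf("pw_%03d", seq_len(p$n_pathways)),
    description = "synthetic pathway",
    genes = sets
  ))
}

#' @export
print.mirlink_sim <- function(x, ...) {
  cat(sprintf(paste0("<mirlink_sim> %d genes x %d samples, %d miRNAs; %d planted DE ",
                     "miRNAs, %d true interactions, %d interaction records, %d gene sets\n"),
              nrow(x$genes), nrow(x$design), nrow(x$mirnas),
              x$truth$n_de_mirnas, x$truth$n_true_interactions,
              nrow(x$interactions), nrow(x$gene_sets)))
  invisible(x)
}
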