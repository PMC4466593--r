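# Shared fixture builders. Everything is generated in code; nothing on disk.

# small but non-trivial simulation used across module tests
small_sim <- function(seed = 11, ...) {
  simulate_dataset(sim_params(
    n_genes = 300, n_mirnas = 30, frac_de_mirnas = 0.2, regulon_size = 10,
    n_pathways = 10, pathway_size_range = c(10, 30), seed = seed, ...
  ))
}

# interaction table straight from a pair list, one perfect source per pair
toy_interactions <- function(mirna, gene, n_sources = 3, consensus = TRUE) {
  flags <- matrix(1L, length(mirna), n_sources,
                  dimnames = list(NULL, sprintf("s%d", seq_len(n_sources))))
  t <- as_interactions(dplyr::bind_cols(tibble::tibble(mirna = mirna, gene = gene),
                                        tibble::as_tibble(as.data.frame(flags))))
  if (consensus) consensus_filter(t, 1) else t
}

# random multi-source table for property tests
random_interactions <- function(n_mirnas, n_genes, n_records, n_sources = 4, seed = 1) {
  withr::with_seed(seed, {
    idx <- sample(n_mirnas * n_genes, n_records)
    flags <- matrix(rbinom(n_records * n_sources, 1L, 0.5), n_records)
    flags[rowSums(flags) == 0L, 1L] <- 1L
    colnames(flags) <- sprintf("s%d", seq_len(n_sources))
    as_interactions(dplyr::bind_cols(
      tibble::tibble(
        mirna = sprintf("m%02d", (idx - 1L) %/% n_genes + 1L),
        gene = sprintf("g%03d", (idx - 1L) %% n_genes + 1L)
      ),
      tibble::as_tibble(as.data.frame(flags))
    ))
  })
}

# independent hypergeometric upper-tail oracle built from plain binomial
# coefficients (no distribution functions)
hyper_tail_oracle <- function(k, N, K, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- max(k, max(0L, n - (N - K))):hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# brute-force BH step-up oracle: direct minimisation over the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  vals <- pmin(1, m * sp / seq_len(m))
  adj_sorted <- vapply(seq_len(m), function(i) min(vals[i:m]), numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 20-gene / 5-miRNA bundle, small enough to enumerate by hand:
# genes g01..g05 shift +2 in adult, g06..g10 shift -2; miRNA mA +2, mB -2;
# mB targets the up-genes and mA the down-genes (inverse coupling)
hand_fixture <- function() {
  design <- generate_design(4, 4)
  gene_ids <- sprintf("g%02d", 1:20)
  mirna_ids <- c("mA", "mB", "mC", "mD", "mE")
  shift_g <- c(rep(2, 5), rep(-2, 5), rep(0, 10))
  shift_m <- c(2, -2, 0, 0, 0)
  adult <- as.numeric(design$group == "adult")
  withr::with_seed(99, {
    x_g <- 8 + outer(shift_g, adult) + matrix(rnorm(20 * 8, 0, 0.05), 20)
    x_m <- 8 + outer(shift_m, adult) + matrix(rnorm(5 * 8, 0, 0.05), 5)
  })
  to_expr <- function(x, ids) {
    colnames(x) <- design$sample_id
    rownames(x) <- ids
    df <- tibble::as_tibble(as.data.frame(x))
    as_expression(dplyr::bind_cols(tibble::tibble(feature_id = ids), df))
  }
  interactions <- as_interactions(tibble::tibble(
    mirna = c("mA", "mA", "mA", "mB", "mB", "mB", "mC", "mC", "mD"),
    gene  = c("g06", "g07", "g08", "g01", "g02", "g03", "g12", "g11", "g15"),
    s1    = c(1, 1, 1, 1, 0, 1, 1, 1, 0),
    s2    = c(1, 1, 1, 1, 1, 1, 1, 0, 1),
    s3    = c(0, 1, 0, 0, 1, 1, 0, 0, 1)
  ))
  gene_sets <- as_gene_sets(tibble::tibble(
    set_name = c("pw_up", "pw_down", "pw_other"),
    description = "hand fixture",
    genes = list(gene_ids[1:5], gene_ids[6:10], gene_ids[13:16])
  ))
  list(genes = to_expr(x_g, gene_ids), mirnas = to_expr(x_m, mirna_ids),
       design = design, interactions = interactions, gene_sets = gene_sets,
       universe = gene_ids)
}
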