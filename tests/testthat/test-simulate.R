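test_that("design generation labels and orders samples, rejects degenerate groups", {
  d <- generate_design(4, 4)
  expect_equal(nrow(d), 8)
  expect_equal(as.character(table(d$group)[c("young", "adult")]), c("4", "4"))
  d2 <- generate_design(2, 2)
  expect_equal(sum(d2$group == "young"), 2)
  expect_error(generate_design(1, 4), class = "mirlink_invalid_design")
  expect_error(generate_design(4, 0), class = "mirlink_invalid_design")
})

test_that("an identical seed reproduces the dataset bit-for-bit, on disk too", {
  s1 <- small_sim(seed = 7)
  s2 <- small_sim(seed = 7)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$gene_sets, s2$gene_sets)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_fixture(s1, d1); f2 <- write_fixture(s2, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("matrices honour the declared design and feature counts", {
  s <- small_sim(seed = 3)
  expect_equal(ncol(s$genes) - 1L, 8L)
  expect_equal(ncol(s$mirnas) - 1L, 8L)
  expect_equal(nrow(s$genes), 300L)
  expect_equal(nrow(s$mirnas), 30L)
  expect_setequal(names(s$genes)[-1], s$design$sample_id)
})

test_that("null coupling with no independent effects plants no DE genes", {
  s <- small_sim(seed = 5, coupling_beta = 0, frac_de_genes_indep = 0)
  expect_equal(nrow(s$truth$de_genes_expected), 0L)
})

test_that("noiseless sources flag every true pair ten times and nothing else", {
  s <- simulate_dataset(sim_params(
    n_genes = 200, n_mirnas = 20, frac_de_mirnas = 0.2, regulon_size = 10,
    n_sources = 10, source_tpr = 1, source_fpr = 0, n_pathways = 5,
    pathway_size_range = c(5, 20), seed = 9
  ))
  expect_equal(nrow(s$interactions), s$truth$n_true_interactions)
  expect_true(all(s$interactions$support == 10L))
  got <- paste(s$interactions$mirna, s$interactions$gene)
  planted <- paste(s$truth$regulons$mirna, s$truth$regulons$gene)
  expect_setequal(got, planted)
})

test_that("positive coupling plants the inverse direction on regulon genes", {
  s <- small_sim(seed = 13, frac_de_genes_indep = 0)
  truth <- s$truth
  reg_dir <- setNames(truth$de_mirnas$direction, truth$de_mirnas$mirna)
  gene_dir <- setNames(truth$de_genes_expected$direction, truth$de_genes_expected$gene)
  expect_true(all(
    gene_dir[truth$regulons$gene] != reg_dir[truth$regulons$mirna]
  ))
  # and the planted shift sizes are -beta * regulator shift
  shift <- setNames(truth$de_genes_expected$shift, truth$de_genes_expected$gene)
  mshift <- setNames(truth$de_mirnas$shift, truth$de_mirnas$mirna)
  expect_equal(unname(shift[truth$regulons$gene]),
               unname(-1 * mshift[truth$regulons$mirna]))
})

test_that("per-source flag rates on true pairs match the nominal TPR", {
  s <- simulate_dataset(sim_params(
    n_genes = 400, n_mirnas = 40, frac_de_mirnas = 0.5, regulon_size = 10,
    n_sources = 10, source_tpr = 0.8, source_fpr = 0, n_pathways = 2,
    pathway_size_range = c(5, 10), seed = 21
  ))
  truth_keys <- paste(s$truth$regulons$mirna, s$truth$regulons$gene)
  rows <- s$interactions[paste(s$interactions$mirna, s$interactions$gene) %in% truth_keys, ]
  src <- as.matrix(rows[, grep("^src_", names(rows))])
  n_true <- nrow(s$truth$regulons)
  # records with zero flags are dropped, so add them back as all-zero rows
  miss <- n_true - nrow(src)
  rates <- colSums(src) / n_true
  ci <- 2.576 * sqrt(0.8 * 0.2 / n_true)
  expect_true(all(abs(rates - 0.8) < ci + miss / n_true))
})

test_that("infeasible regulon allocation is rejected up front", {
  expect_error(
    sim_params(n_genes = 50, n_mirnas = 20, frac_de_mirnas = 1, regulon_size = 10),
    class = "mirlink_config_error"
  )
  expect_error(sim_params(noise_sd = 0), class = "mirlink_invalid_argument")
  expect_error(sim_params(n_sources = 1), class = "mirlink_invalid_argument")
})

test_that("fixtures round-trip losslessly through the package readers", {
  s <- small_sim(seed = 17)
  dir <- withr::local_tempdir()
  paths <- write_fixture(s, dir)
  expect_length(paths, 7)
  back <- read_fixture(dir)
  expect_equal(as.data.frame(back$genes), as.data.frame(s$genes))
  expect_equal(as.data.frame(back$mirnas), as.data.frame(s$mirnas))
  expect_equal(back$design$group, s$design$group)
  expect_equal(as.data.frame(back$interactions), as.data.frame(s$interactions))
  expect_equal(back$gene_sets$genes, s$gene_sets$genes)
  expect_identical(back$universe, s$universe)
  # linear-scale export is the exact anti-log
  write_fixture(s, dir, linear = TRUE)
  lin <- read_fixture(dir, linear = TRUE)
  expect_equal(as.matrix(lin$genes[-1]), 2^as.matrix(s$genes[-1]), tolerance = 1e-12)
})

test_that("GMT export keeps >= 3 fields per line", {
  s <- small_sim(seed = 19)
  dir <- withr::local_tempdir()
  write_fixture(s, dir)
  lines <- readLines(file.path(dir, "pathways.gmt"))
  expect_true(all(lengths(strsplit(lines, "\t")) >= 3))
})
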