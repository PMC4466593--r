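test_that("inverse intersections follow direct lookup", {
  t <- toy_interactions("m1", "g1")
  res <- inverse_intersection(up_genes = c("g1", "g2"), down_genes = character(),
                              up_mirnas = character(), down_mirnas = "m1", t = t)
  expect_equal(res$up_gene_down_mirna, "g1")
  expect_equal(res$down_gene_up_mirna, character())
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$pairing, "up_gene_down_mirna")
  # disjoint targets and DE genes -> empty sets
  none <- inverse_intersection("gX", "gY", "mA", "mB", t)
  expect_equal(none$up_gene_down_mirna, character())
  expect_equal(nrow(none$pairs), 0)
})

test_that("inverse pair lists match a brute-force double loop", {
  t <- consensus_filter(random_interactions(8, 30, 80, seed = 31), 2)
  withr::with_seed(32, {
    up_g <- sample(sprintf("g%03d", 1:30), 10)
    down_g <- sample(setdiff(sprintf("g%03d", 1:30), up_g), 10)
    up_m <- sample(sprintf("m%02d", 1:8), 3)
    down_m <- sample(setdiff(sprintf("m%02d", 1:8), up_m), 3)
  })
  res <- inverse_intersection(up_g, down_g, up_m, down_m, t)
  brute <- list(ug_dm = character(), dg_um = character())
  for (i in seq_len(nrow(t))) {
    for (g in up_g) if (t$gene[i] == g && t$mirna[i] %in% down_m)
      brute$ug_dm <- c(brute$ug_dm, paste(t$mirna[i], g))
    for (g in down_g) if (t$gene[i] == g && t$mirna[i] %in% up_m)
      brute$dg_um <- c(brute$dg_um, paste(t$mirna[i], g))
  }
  got <- split(paste(res$pairs$mirna, res$pairs$gene), res$pairs$pairing)
  expect_setequal(got$up_gene_down_mirna %||% character(), unique(brute$ug_dm))
  expect_setequal(got$down_gene_up_mirna %||% character(), unique(brute$dg_um))
})

test_that("inverse intersections shrink as the consensus threshold rises", {
  t <- random_interactions(8, 30, 120, n_sources = 5, seed = 33)
  up_g <- sprintf("g%03d", 1:15); down_m <- sprintf("m%02d", 1:4)
  sizes <- vapply(1:5, function(k) {
    res <- inverse_intersection(up_g, character(), character(), down_m,
                                consensus_filter(t, k))
    length(res$up_gene_down_mirna)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("pathway overlaps are plain direction-paired intersections", {
  ov <- overlap_pathways(gene_up = c("A", "B", "C"), gene_down = c("X", "Y"),
                         mirna_up = c("Y", "Z"), mirna_down = c("B", "C", "D"))
  expect_equal(ov$up_gene_down_mirna, c("B", "C"))
  expect_equal(ov$down_gene_up_mirna, "Y")
  empty <- overlap_pathways(character(), c("X"), c("X"), character())
  expect_equal(empty$up_gene_down_mirna, character())
  same <- overlap_pathways(c("A", "B"), "X", c("B"), "X", pairing = "same")
  expect_equal(same$up_up, "B")
})

test_that("enriched-miRNA overlap pairs DE miRNAs with the opposite gene list", {
  em <- enriched_mirna_overlap(
    up_mirnas = c("m1", "m2"), down_mirnas = c("m3", "m4"),
    enriched_in_up = c("m3", "m9"), enriched_in_down = c("m1", "m8")
  )
  expect_equal(em$down_mirnas_enriched_in_up_genes, "m3")
  expect_equal(em$up_mirnas_enriched_in_down_genes, "m1")
  none <- enriched_mirna_overlap(character(), character(), c("m1"), c("m2"))
  expect_equal(none$down_mirnas_enriched_in_up_genes, character())
})

test_that("summary counts are cardinalities of the emitted sets", {
  s <- small_sim(seed = 41)
  run <- suppressWarnings(suppressMessages(run_pipeline(s, analysis_config(
    gene_filter = filter_spec("recovery"),
    mirna_filter = filter_spec("recovery"), seed = 41
  ))))
  cnt <- run$summary$counts
  sets <- run$summary$sets
  expect_equal(cnt$up[cnt$block == "mRNA" & cnt$quantity == "genes"],
               length(sets$up_genes))
  expect_equal(cnt$down[cnt$block == "common" & cnt$quantity == "genes"],
               length(sets$inverse_down_gene_up_mirna))
  expect_equal(cnt$up[cnt$block == "common" & cnt$quantity == "pathways"],
               length(sets$overlap_pathways_up))
  # invariants: inverse gene sets are subsets of the DE gene sets
  expect_true(all(sets$inverse_up_gene_down_mirna %in% sets$up_genes))
  expect_true(all(sets$inverse_down_gene_up_mirna %in% sets$down_genes))
  expect_true(all(sets$overlap_pathways_up %in% sets$gene_pathways_up))
  expect_true(all(sets$overlap_pathways_up %in% sets$mirna_pathways_down))
})

test_that("summaries refuse enrichment stages run on different universes", {
  s <- small_sim(seed = 43)
  cfg <- analysis_config(gene_filter = filter_spec("recovery"),
                         mirna_filter = filter_spec("recovery"), seed = 43)
  run <- suppressMessages(run_pipeline(s, cfg))
  other <- suppressMessages(pathway_enrichment(
    run$summary$sets$up_genes, s$gene_sets, s$universe[1:100]
  ))
  expect_error(
    build_summary(run$gene_de, run$mirna_de, other, run$gene_enrich$down,
                  run$mirna_enrich$up, run$mirna_enrich$down,
                  run$bindingsite$up, run$bindingsite$down,
                  run$inverse, cfg),
    class = "mirlink_consistency_error"
  )
})
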