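universe20 <- sprintf("g%02d", 1:20)

test_that("fold enrichment and the hypergeometric tail match closed forms", {
  res <- fisher_overrep(universe20[1:8], universe20[1:5], universe20)
  # N=20, K=5, n=8, k=5 -> fold = (5/8)/(5/20) = 2.5
  expect_equal(res$k, 5)
  expect_equal(res$fold_enrichment, 2.5)
  # hand case with k = 4: drop one set member from the query
  res4 <- fisher_overrep(c(universe20[1:4], universe20[6:9]), universe20[1:5], universe20)
  expect_equal(res4$k, 4)
  expect_equal(res4$fold_enrichment, (4 / 8) / (5 / 20))
  oracle <- sum(choose(5, 4:5) * choose(15, 8 - (4:5))) / choose(20, 8)
  expect_equal(res4$p_raw, oracle, tolerance = 1e-12)
  # saturation: query = universe
  sat <- fisher_overrep(universe20, universe20[1:5], universe20)
  expect_equal(sat$k, sat$K)
  expect_equal(sat$p_raw, 1)
  expect_equal(sat$fold_enrichment, 1)
})

test_that("the exact test agrees with stats::fisher.test one-sided", {
  withr::with_seed(10, {
    for (i in 1:20) {
      N <- sample(20:80, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      u <- sprintf("u%03d", 1:N)
      set <- sample(u, K); q <- sample(u, n)
      res <- fisher_overrep(q, set, u)
      tab <- matrix(c(res$k, res$K - res$k, res$n - res$k,
                      res$N - res$K - res$n + res$k), 2)
      expect_equal(res$p_raw, fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("the tail probability is nonincreasing in the overlap", {
  ps <- vapply(0:5, function(k) mirlink:::hyper_upper_tail(k, 20, 5, 8), numeric(1))
  expect_true(all(diff(ps) <= 0))
  # overrepresentation direction agrees with the score
  withr::with_seed(11, {
    for (i in 1:20) {
      N <- 50; K <- sample(2:25, 1); n <- sample(2:25, 1)
      u <- sprintf("u%02d", 1:N)
      res <- fisher_overrep(sample(u, n), sample(u, K), u)
      if (!is.na(res$fold_enrichment) && res$fold_enrichment != 1) {
        expect_equal(res$fold_enrichment > 1, res$k / res$n > res$K / res$N)
      }
    }
  })
})

test_that("an empty query yields the null row rather than an error", {
  res <- fisher_overrep(character(), universe20[1:5], universe20)
  expect_equal(res$k, 0)
  expect_equal(res$n, 0)
  expect_equal(res$p_raw, 1)
  expect_true(is.na(res$fold_enrichment))
  expect_error(fisher_overrep("a", "b", character()), class = "mirlink_invalid_argument")
})

test_that("collection-level BH uses the whole collection as the family", {
  sets1 <- as_gene_sets(tibble::tibble(set_name = "s1", description = "",
                                       genes = list(universe20[1:5])))
  res1 <- pathway_enrichment(universe20[1:8], sets1, universe20)
  expect_equal(res1$p_adj, res1$p_raw)  # m = 1
  # query disjoint from all sets: k = 0 rows retained, none significant
  sets2 <- as_gene_sets(tibble::tibble(set_name = c("a", "b"), description = "",
                                       genes = list(universe20[1:3], universe20[4:6])))
  res0 <- pathway_enrichment(universe20[10:15], sets2, universe20)
  expect_equal(nrow(res0), 2)
  expect_true(all(res0$k == 0) && !any(res0$significant))
  # empty collection -> empty result
  empty <- pathway_enrichment(universe20[1:3],
                              as_gene_sets(tibble::tibble(set_name = character(),
                                                          description = character(),
                                                          genes = list())),
                              universe20)
  expect_equal(nrow(empty), 0)
})

test_that("a pathway built from planted DE genes ranks first and is significant", {
  s <- simulate_dataset(sim_params(
    n_genes = 500, n_mirnas = 20, frac_de_mirnas = 0.2, regulon_size = 15,
    coupling_beta = 1.5, noise_sd = 0.3, n_pathways = 20,
    pathway_size_range = c(15, 40), pathway_de_bias = 30, seed = 12
  ))
  expected <- s$truth$de_genes_expected$gene
  sets <- as_gene_sets(dplyr::bind_rows(
    s$gene_sets,
    tibble::tibble(set_name = "planted", description = "built from planted DE genes",
                   genes = list(expected))
  ))
  res <- suppressMessages(pathway_enrichment(expected, sets, s$universe))
  expect_equal(res$name[1], "planted")
  expect_true(res$significant[1])
})

test_that("binding-site enrichment composes from single Fisher tests", {
  t <- toy_interactions(c("m1", "m1", "m2", "m2", "m2"),
                        c("g01", "g02", "g03", "g04", "g05"))
  de <- c("g01", "g02", "g06")
  res <- mirna_bindingsite_enrichment(de, t, universe20)
  direct <- fisher_overrep(de, c("g01", "g02"), universe20)
  expect_equal(res$p_raw[res$name == "m1"], direct$p_raw)
  expect_equal(res$k[res$name == "m1"], direct$k)
  # perfect concentration gives the minimal p among tested miRNAs
  expect_equal(res$name[which.min(res$p_raw)], "m1")
  # miRNAs with no in-universe target are skipped, not tested
  t2 <- toy_interactions(c("m1", "m9"), c("g01", "outside_universe"))
  res2 <- suppressMessages(mirna_bindingsite_enrichment(de, t2, universe20))
  expect_false("m9" %in% res2$name)
})

test_that("miRNA pathway enrichment is the enrichment of the target union", {
  t <- toy_interactions(c("m1", "m1", "m2"), c("g01", "g02", "g03"))
  sets <- as_gene_sets(tibble::tibble(set_name = c("hit", "miss"), description = "",
                                      genes = list(c("g01", "g02"), c("g10", "g11"))))
  res <- mirna_pathway_enrichment("m1", t, sets, universe20)
  expect_equal(res$k[res$name == "hit"], 2)
  expect_equal(res$k[res$name == "hit"], res$K[res$name == "hit"])
  expect_true(res$significant[res$name == "hit"])
  expect_equal(attr(res, "query_size"), 2)
  # duplicated miRNA ids change nothing (set semantics)
  res_dup <- mirna_pathway_enrichment(c("m1", "m1"), t, sets, universe20)
  expect_equal(as.data.frame(res_dup), as.data.frame(res))
  # no DE miRNAs: empty query behaviour
  res0 <- mirna_pathway_enrichment(character(), t, sets, universe20)
  expect_true(all(res0$k == 0) && !any(res0$significant))
})
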