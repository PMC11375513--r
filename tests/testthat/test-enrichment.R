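fake_component <- function(u, v = c(sp1 = 0.5), index = 1L) {
  structure(list(index = index, u = u, v = v, d = 1,
                 x_scores = NULL, y_scores = NULL,
                 score_correlation = NA, penalties = c(c1 = 1, c2 = 1),
                 permutation_p = NA_real_, converged = TRUE),
            class = "cca_component")
}

test_that("component gene selection honors rules, ties and padding limits", {
  u <- c(a = 0.5, b = -0.9, c = 0, d = 0.2, e = -0.2, f = 0.9)
  comp <- fake_component(u)
  expect_setequal(component_gene_set(comp, "nonzero"), c("a", "b", "d", "e", "f"))
  # |b| == |f| tie at the cut resolves lexicographically; |d| == |e| likewise
  expect_identical(component_gene_set(comp, "top_n", n = 1), "b")
  expect_identical(component_gene_set(comp, "top_n", n = 4),
                   c("b", "f", "a", "d"))
  # n beyond the nonzero count returns all nonzeros, no padding
  expect_length(component_gene_set(comp, "top_n", n = 50), 5)
  expect_error(component_gene_set(fake_component(c(a = 0, b = 0))),
               "all-zero")
})

test_that("Fisher enrichment matches closed forms on degenerate tables", {
  uni <- paste0("g", 1:40)
  sel <- uni[1:8]
  # zero overlap: P(X >= 0) = 1
  no <- fisher_enrichment(sel, uni[30:35], uni)
  expect_equal(no$p_value, 1)
  expect_equal(no$n_overlap, 0)
  # pathway covering the whole universe: overlap = |selected|, p = 1
  all_in <- fisher_enrichment(sel, c(uni, "outside"), uni)
  expect_equal(all_in$n_overlap, 8)
  expect_equal(all_in$n_pathway_in_universe, 40)
  expect_equal(all_in$p_value, 1)
  expect_error(fisher_enrichment(character(), uni[1:5], uni), "empty selected")
  expect_error(fisher_enrichment(sel, uni[1:5], character()), "empty universe")
  expect_error(fisher_enrichment(c(sel, "alien"), uni[1:5], uni), "contained")
})

test_that("Fisher enrichment equals the explicit hypergeometric sum", {
  # the worked 100/10/10/5 configuration
  uni <- paste0("g", 1:100)
  sel <- uni[1:10]
  path <- c(uni[1:5], uni[90:94])
  fe <- fisher_enrichment(sel, path, uni)
  expect_equal(fe$n_overlap, 5)
  expect_equal(fe$p_value, hyper_tail_oracle(5, 10, 100, 10),
               tolerance = 1e-14)
  # random small tables
  set.seed(21)
  for (i in 1:30) {
    N <- sample(10:50, 1)
    u <- paste0("g", seq_len(N))
    s <- sample(u, sample(2:(N - 1), 1))
    p <- sample(u, sample(2:(N - 1), 1))
    fe <- fisher_enrichment(s, p, u)
    k <- length(intersect(s, p))
    expect_equal(fe$p_value,
                 hyper_tail_oracle(k, length(p), N, length(s)),
                 tolerance = 1e-12)
  }
})

test_that("enrichment agrees with stats::fisher.test one-sided p", {
  uni <- paste0("g", 1:60)
  set.seed(22)
  sel <- sample(uni, 12); path <- sample(uni, 15)
  fe <- fisher_enrichment(sel, path, uni)
  tab <- table(factor(uni %in% sel, c(TRUE, FALSE)),
               factor(uni %in% path, c(TRUE, FALSE)))
  expect_equal(fe$p_value,
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("shared/unique classification partitions the enriched union", {
  eo <- data.frame(component = c("EOC1", "EOC1", "EOC2"),
                   pathway = c("P1", "P2", "P3"),
                   enriched = c(TRUE, TRUE, FALSE))
  lo <- data.frame(component = c("LOC4", "LOC1"),
                   pathway = c("P1", "P4"),
                   enriched = c(TRUE, TRUE))
  cls <- classify_shared_unique(eo, lo)
  expect_identical(cls$category[cls$pathway == "P1"], "shared")
  expect_identical(cls$category[cls$pathway == "P2"], "EO-only")
  expect_identical(cls$category[cls$pathway == "P4"], "LO-only")
  expect_false("P3" %in% cls$pathway)  # never enriched -> absent
  expect_false(anyDuplicated(cls$pathway) > 0)
  empty <- classify_shared_unique(eo[0, ], lo[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("species link to pathways of components carrying their weight", {
  comp1 <- fake_component(c(gA = 1), v = c(sp1 = 0.4, sp2 = 0, sp3 = -0.1))
  comp2 <- fake_component(c(gB = 1), v = c(sp1 = 0, sp2 = 0, sp3 = 0.2),
                          index = 2L)
  rec <- data.frame(
    component = c("LOC1", "LOC1", "LOC2", "LOC2"),
    pathway = c("P1", "P2", "P1", "P3"),
    enriched = c(TRUE, TRUE, FALSE, TRUE))
  links <- species_pathway_links(list(comp1, comp2), rec, phenotype = "LO")
  # sp2 has zero weight everywhere: never linked
  expect_false("sp2" %in% links$species)
  # sp1 nonzero only in component 1 -> its 2 enriched pathways
  expect_setequal(links$pathway[links$species == "sp1"], c("P1", "P2"))
  # sp3 nonzero in both -> P1, P2 (LOC1) and P3 (LOC2)
  expect_setequal(links$pathway[links$species == "sp3"], c("P1", "P2", "P3"))
  counts <- species_pathway_counts(links)
  expect_equal(counts$n_pathways[counts$species == "sp3"], 3L)
})

test_that("end-to-end: a planted species-support links to a planted gene set", {
  sim <- generate_paired_omics(80, 150, 40, 1, c(12, 6), 4, 0.8, seed = 31)
  x <- standardize(sim$expression)
  y <- standardize(clr_transform(sim$abundance))
  fit <- fit_sparse_cca(x, y, K = 1, c1 = 0.25 * sqrt(150),
                        c2 = 0.35 * sqrt(40))
  gs <- generate_genesets(sim$truth, n_sets = 15, set_size = 10,
                          overlap_fraction = 1, seed = 32)
  rec <- enrich_components(fit, gs, phenotype = "LO")
  expect_true(rec$enriched[rec$pathway == "PLANTED_C1"])
  links <- species_pathway_links(fit, rec, phenotype = "LO")
  planted_sp <- sim$truth$species_ids[sim$truth$species_supports[[1]]]
  linked_sp <- unique(links$species[links$pathway == "PLANTED_C1"])
  expect_gt(length(intersect(linked_sp, planted_sp)), 0)
})

test_that("decoy enrichment p-values are valid (conservative) under the null", {
  # discrete exact tests guarantee P(p <= t) <= t, not an exact 5% rate
  set.seed(41)
  uni <- sprintf("g%03d", 1:200)
  ps <- replicate(500, {
    sel <- sample(uni, 20)
    path <- sample(uni, 12)
    fisher_enrichment(sel, path, uni)$p_value
  })
  for (t in c(0.01, 0.05, 0.1, 0.25)) {
    # binomial slack: 3 sd above the nominal level at 500 draws
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 500))
  }
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("GMT parsing agrees with the fgsea reader", {
  skip_if_not_installed("fgsea")
  sets <- list(ALPHA = c("g1", "g2", "g3"), BETA = c("g2", "g9"))
  gs <- gene_set_collection(sets, descriptions = c("one", "two"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  ref <- fgsea::gmtPathways(path)
  expect_identical(ref, gs$sets)
})
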