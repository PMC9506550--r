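# Annotation, hypergeometric enrichment, BH-FDR, pathway impact.

test_that("annotation respects tolerance and polarity", {
  lib <- load_compound_library()
  target <- lib$theoretical_mz[lib$compound_id == 21] # caffeic acid, [M-H]-
  q <- tibble::tibble(mz = c(target * (1 + 2e-6), target * (1 + 20e-6)),
                      polarity = "negative")
  ann <- annotate_mz_list(q, db = lib, tol_ppm = 5)
  expect_true("21" %in% ann$compound_id[ann$mz == q$mz[1]])
  expect_false(q$mz[2] %in% ann$mz)
  # wrong polarity never matches
  annp <- annotate_mz_list(tibble::tibble(mz = target, polarity = "positive"),
                           db = lib, tol_ppm = 5)
  expect_false("21" %in% annp$compound_id)
})

test_that("BH adjustment matches the hand step-up calculation", {
  # hand calculation: p_(i) * n / i, cumulative minimum from the largest
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.005, 0.04, 0.8)),
               c(0.015, 0.06, 0.8))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric p matches exact enumeration on a small universe", {
  # universe 20, one pathway of 5, significant = the 5 pathway members
  mem <- tibble::tibble(pathway = "P", compound_id = as.character(1:5))
  g <- pathway_graph(mem)
  res <- enrich_pathways(as.character(1:5), as.character(1:20), graph = g,
                         n_perm = 0)
  expect_equal(res$p_raw, 1 / choose(20, 5), tolerance = 1e-12)
  # exhaustive oracle: enumerate all C(20,5) significant sets
  sets <- utils::combn(20, 5)
  oracle <- mean(apply(sets, 2, function(s) sum(s <= 5) >= 5))
  expect_equal(res$p_raw, oracle, tolerance = 1e-12)
  # zero hits -> p = 1
  res0 <- enrich_pathways(as.character(6:10), as.character(1:20), graph = g,
                          n_perm = 0)
  expect_identical(res0$p_raw, 1)
  expect_identical(res0$hits, 0L)
  expect_error(enrich_pathways("99", as.character(1:20), graph = g),
               "missing from the reference")
})

test_that("permutation p agrees with hypergeometric within MC error", {
  set.seed(41)
  mem <- tibble::tibble(
    pathway = rep(c("A", "B"), c(6, 10)),
    compound_id = as.character(1:16))
  g <- pathway_graph(mem)
  universe <- as.character(1:40)
  sig <- as.character(c(1:4, 20:27))
  B <- 4000
  res <- enrich_pathways(sig, universe, graph = g, n_perm = B, seed = 5)
  for (i in seq_len(nrow(res))) {
    p <- res$p_raw[i]
    expect_lt(abs(res$p_perm[i] - p),
              3 * sqrt(p * (1 - p) / B) + 2 / B,
              label = res$pathway[i])
  }
})

test_that("enrichment p is invariant under compound relabeling and monotone", {
  mem <- tibble::tibble(pathway = rep("P", 6),
                        compound_id = as.character(1:6))
  g <- pathway_graph(mem)
  universe <- as.character(1:30)
  sig <- as.character(c(1, 2, 3, 15, 16))
  base <- enrich_pathways(sig, universe, graph = g, n_perm = 0)
  # relabel: apply a permutation to all ids consistently
  set.seed(42)
  relab <- setNames(sample(as.character(101:130)), universe)
  g2 <- pathway_graph(tibble::tibble(pathway = "P",
                                     compound_id = relab[mem$compound_id]))
  res2 <- enrich_pathways(relab[sig], relab[universe], graph = g2,
                          n_perm = 0)
  expect_equal(res2$p_raw, base$p_raw, tolerance = 1e-12)
  # adding a pathway hit never increases p
  sig_plus <- c(sig, "4")
  res3 <- enrich_pathways(sig_plus, universe, graph = g, n_perm = 0)
  expect_lte(res3$p_raw, base$p_raw)
})

test_that("null significant sets are calibrated", {
  set.seed(43)
  graph <- load_pathway_graph()
  universe <- unique(graph$membership$compound_id)
  hits <- replicate(400, {
    sig <- sample(universe, 10)
    res <- enrich_pathways(sig, universe, graph = graph, n_perm = 0)
    mean(res$p_raw < 0.05)
  })
  # hypergeometric p is discrete and conservative, so the rejection rate
  # stays at or below the nominal level but not far below zero
  expect_lt(mean(hits), 0.08)
})

test_that("pathway impact is the normalised betweenness of hit nodes", {
  # 5-node path graph a-b-c-d-e: betweenness (0, 3, 4, 3, 0), sum 10
  mem <- tibble::tibble(pathway = "P", compound_id = letters[1:5])
  edges <- tibble::tibble(pathway = "P", from = letters[1:4],
                          to = letters[2:5])
  g <- pathway_graph(mem, edges)
  expect_equal(pathway_impact(g, "c")$impact, 4 / 10)
  expect_equal(pathway_impact(g, c("b", "c"))$impact, 7 / 10)
  expect_equal(pathway_impact(g, letters[1:5])$impact, 1)
  expect_identical(pathway_impact(g, character(0))$impact, 0)
  # impact always within [0, 1] on the bundled graph
  graph <- load_pathway_graph()
  imp <- pathway_impact(graph, sample(unique(graph$membership$compound_id),
                                      30))
  expect_true(all(imp$impact >= 0 & imp$impact <= 1))
})

test_that("bundled graph has twelve non-empty pathways", {
  g <- load_pathway_graph()
  expect_identical(length(g$graphs), 12L)
  expect_true(all(vapply(g$graphs, igraph::vcount, numeric(1)) > 0))
  # every member compound exists in the bundled library
  lib <- load_compound_library()
  expect_true(all(g$membership$compound_id %in%
                    as.character(lib$compound_id)))
})
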