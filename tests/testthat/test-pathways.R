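toy_gsc <- function() {
  bg <- sprintf("g%02d", 1:20)
  geneset_collection(
    list(P1 = bg[1:5], P2 = bg[6:12], ALL = bg),
    background = bg, quiet = TRUE
  )
}

# hub with 4 neighbours, 3 inside pathway P1 (5 of 20 background genes)
toy_enrich_net <- function() {
  as_ppi_network(edges_df(
    "hub", "g01", "hub", "g02", "hub", "g03", "hub", "g06"
  ), quiet = TRUE)
}

test_that("gene-set collections restrict to the background and drop empties", {
  expect_message(
    gsc <- geneset_collection(
      list(A = c("x", "y"), B = c("zz")),
      background = c("x", "y", "w")
    ),
    "dropped 1 gene set"
  )
  expect_equal(names(gsc$sets), "A")
  expect_setequal(gsc$sets$A, c("x", "y"))
})

test_that("neighbour enrichment matches the hypergeometric enumeration", {
  # background 20, pathway of 5, hub with 4 neighbours of which 3 in pathway
  res <- enrich_neighbours("hub", toy_enrich_net(), toy_gsc(), fdr = 0.05)
  row <- res[res$pathway == "P1", ]
  expect_equal(row$overlap, 3L)
  expect_equal(row$pvalue, 155 / 4845, tolerance = 1e-12)
  expect_equal(row$pvalue, hyper_tail_enum(3, 5, 4, 20), tolerance = 1e-12)

  # pathway = entire background: overlap is certain, p = 1
  expect_equal(res$pvalue[res$pathway == "ALL"], 1)
})

test_that("disjoint neighbourhoods yield no significant enrichment", {
  net <- as_ppi_network(edges_df("hub", "g13", "hub", "g14"), quiet = TRUE)
  gsc <- geneset_collection(
    list(P1 = sprintf("g%02d", 1:5)),
    background = sprintf("g%02d", 1:20), quiet = TRUE
  )
  res <- enrich_neighbours("hub", net, gsc, fdr = 0.05)
  expect_equal(res$pvalue, 1)
  expect_false(any(res$qsignificant))
})

test_that("a hub with no in-background neighbour gets p = 1 everywhere", {
  net <- as_ppi_network(edges_df("hub", "outside"), quiet = TRUE)
  gsc <- toy_gsc()
  res <- enrich_neighbours("hub", net, gsc)
  expect_true(all(res$pvalue == 1))
})

test_that("significant pathway sets use set semantics and grow with fdr", {
  sc <- synthetic_scenario(n_nodes = 80, n_planted = 4, hub_degree = 5, seed = 3)
  net <- make_network(sc)
  gsc <- make_genesets(sc, net)
  p <- planted_hubs(net)
  res <- enrich_neighbours(p$hubs1, net, gsc, fdr = 0.01)
  sig <- significant_pathways(res)
  expect_equal(anyDuplicated(sig), 0)
  expect_true(all(startsWith(sig, "planted_pathway")))
  expect_gte(length(sig), 3) # planted neighbourhoods tile their pathways

  res05 <- enrich_neighbours(p$hubs1, net, gsc, fdr = 0.05)
  expect_true(all(sig %in% significant_pathways(res05))) # monotone in fdr

  # empty result maps to the empty set
  expect_equal(significant_pathways(res[0, ]), character(0))
})

test_that("enrichment is invariant to hub and pathway ordering", {
  sc <- synthetic_scenario(n_nodes = 80, n_planted = 3, hub_degree = 5, seed = 13)
  net <- make_network(sc)
  gsc <- make_genesets(sc, net)
  p <- planted_hubs(net)
  a <- enrich_neighbours(p$hubs1, net, gsc)
  b <- enrich_neighbours(rev(p$hubs1), net, gsc)
  key <- function(x) x[order(x$hub, x$pathway), c("hub", "pathway", "pvalue")]
  expect_equal(as.data.frame(key(a)), as.data.frame(key(b)))
})

test_that("pathway-overlap null: empty reference and planted fixture", {
  sc <- synthetic_scenario(n_nodes = 80, n_planted = 4, hub_degree = 5, seed = 23)
  net <- make_network(sc)
  gsc <- make_genesets(sc, net)
  p <- planted_hubs(net)

  empty <- pathway_overlap_null(net, character(0), p$hubs2, gsc,
    n_rep = 5, seed = 1
  )
  expect_equal(empty$samples, rep(0, 5))
  expect_equal(empty$observed, 0)
  expect_equal(empty$empirical_p, 1)

  ref <- significant_pathways(enrich_neighbours(p$hubs1, net, gsc))
  nd <- pathway_overlap_null(net, ref, p$hubs2, gsc, n_rep = 30, seed = 2)
  expect_true(all(nd$samples >= 0 & nd$samples <= length(ref)))
  expect_true(all(nd$samples == round(nd$samples)))
  expect_gt(nd$observed, nd$mean)
  expect_lt(nd$empirical_p, 0.05)
})

test_that("shared-neighbour gene-set test matches the brute-force oracle", {
  sc <- synthetic_scenario(
    n_nodes = 60, n_planted = 3, hub_degree = 5,
    shared_neighbourhood_fraction = 0.8, seed = 33
  )
  net <- make_network(sc)
  gsc <- make_genesets(sc, net)
  p <- planted_hubs(net)
  special <- unlist(p$partners1, use.names = FALSE)[1:8]

  res <- shared_neighbour_geneset_test(
    p$hubs1, p$hubs2, net,
    restrict_to = names(gsc$sets)[startsWith(names(gsc$sets), "planted")],
    gsc = gsc, special_genes = special
  )
  expect_lte(res$g, min(res$n, res$m))
  expect_equal(
    res$pvalue_overlap,
    hyper_tail_enum(res$g, res$n, res$m, res$N),
    tolerance = 1e-9
  )
  expect_equal(
    res$pvalue_special,
    hyper_tail_enum(res$special_hits, res$special_n, res$g, res$background_size),
    tolerance = 1e-9
  )

  # special genes disjoint from the intersection: p = 1
  res2 <- shared_neighbour_geneset_test(
    p$hubs1, p$hubs2, net,
    restrict_to = NULL, gsc = gsc, special_genes = "hubA01"
  )
  expect_equal(res2$special_hits, 0)
  expect_equal(res2$pvalue_special, 1)
})

test_that("empty restricted neighbour sets give a defined null result", {
  net <- as_ppi_network(edges_df("h1", "x", "h2", "y"), quiet = TRUE)
  gsc <- geneset_collection(list(P = c("q1", "q2")),
    background = c("x", "y", "q1", "q2"), quiet = TRUE
  )
  res <- shared_neighbour_geneset_test("h1", "h2", net,
    restrict_to = "P", gsc = gsc
  )
  expect_equal(res$g, 0)
  expect_equal(res$pvalue_overlap, 1)
})
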