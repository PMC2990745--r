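test_that("hypergeometric upper tail matches hand enumeration", {
  expect_equal(hypergeom_upper_tail(0, 3, 3, 10), 1.0)
  # C(3,2)C(7,1) + C(3,3)C(7,0) over C(10,3)
  expect_equal(hypergeom_upper_tail(2, 3, 3, 10), 22 / 120, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(4, 3, 3, 10), "0 <= g")
  expect_error(hypergeom_upper_tail(2, 3, 11, 10), "0 <= g")
})

test_that("hypergeometric tail is numerically stable at interactome scale", {
  p <- hypergeom_upper_tail(114, 191, 238, 5470)
  expect_lt(p, 2.2e-16)
  expect_gt(p, 0)
  # large-N sanity: no underflow to NaN
  expect_true(is.finite(hypergeom_upper_tail(500, 1000, 2000, 1e5)))
})

test_that("binomial upper tail matches closed forms", {
  expect_equal(binom_upper_tail(0, 5, 0.5), 1.0)
  expect_equal(binom_upper_tail(6, 6, 0.5), 1 / 64) # all successes
  expect_equal(binom_upper_tail(3, 4, 0.5), 5 / 16, tolerance = 1e-12)
  expect_error(binom_upper_tail(5, 4, 0.5), "0 <= k")
  expect_error(binom_upper_tail(1, 4, 0), "0 < p")
})

test_that("PO score arithmetic and edge cases", {
  r <- po_from_counts(4, 65, 72)
  expect_equal(r$PO, (4 / 65 + 4 / 72) / 2, tolerance = 1e-12)

  ident <- po_score(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(ident$PO, 1)
  disjoint <- po_score(c("a", "b"), c("x", "y", "z"))
  expect_equal(disjoint$PO, 0)
  expect_equal(disjoint$L1, 2)
  expect_equal(disjoint$L2, 3)
  expect_error(po_score(character(0), "a"), "non-empty")
})

test_that("neighbour-overlap tests evaluate pairs and apply BH globally", {
  net <- twin_hub_net(n_partners = 10, n_filler = 88) # 100 nodes
  tests <- neighbour_overlap_matrix("hubA", "hubB", net, N = 100, fdr = 0.05)
  expect_equal(nrow(tests), 1)
  expect_equal(tests$g, 10)
  expect_equal(tests$pvalue, hypergeom_upper_tail(10, 10, 10, 100))
  expect_true(tests$significant)

  # disjoint neighbourhoods: certain-overlap-of-zero, never significant
  net2 <- as_ppi_network(edges_df("h1", "x", "h2", "y"), quiet = TRUE)
  t2 <- neighbour_overlap_matrix("h1", "h2", net2, N = 10)
  expect_equal(t2$pvalue, 1)
  expect_false(t2$significant)

  # BH is applied across all L1 x L2 tests of the run
  t3 <- neighbour_overlap_matrix(c("hubA", "hubB"), c("hubA", "hubB"),
    net, N = 100, fdr = 0.05
  )
  expect_equal(t3$p_adjusted, p.adjust(t3$pvalue, "BH"))
})

test_that("POT equals 1 for identical lists and for twin neighbourhoods", {
  net <- twin_hub_net(n_partners = 8, n_filler = 40)
  # identical lists: k = L, T terms vacuous
  same <- pot_score(c("hubA", "hubB"), c("hubA", "hubB"), net, N = 500)
  expect_equal(same$POT, 1)
  expect_equal(same$k, 2)

  # disjoint lists, planted identical neighbourhoods: PO = 0, POT = 1
  twin <- pot_score("hubA", "hubB", net, N = 500)
  expect_equal(twin$PO, 0)
  expect_equal(twin$POT, 1)
  expect_equal(twin$T12, 1)
  expect_equal(twin$T21, 1)
})

test_that("POT averaging combines the directional scores", {
  r <- pot_from_counts(k = 0, T12 = 71, T21 = 57, L1 = 100, L2 = 100)
  expect_equal(r$POT12, 0.71)
  expect_equal(r$POT21, 0.57)
  expect_equal(r$POT, 0.64)
})

test_that("POT is symmetric under swapping the lists", {
  net <- er_net(60, 150, seed = 13)
  l1 <- igraph::V(net)$name[1:7]
  l2 <- igraph::V(net)$name[5:14]
  a <- pot_score(l1, l2, net, N = 60)
  b <- pot_score(l2, l1, net, N = 60)
  expect_equal(a$POT12, b$POT21)
  expect_equal(a$POT21, b$POT12)
  expect_equal(a$POT, b$POT)
  expect_gte(a$POT, a$PO)
})

test_that("direction consistency counts sign-matched correlation changes", {
  genes <- c("hub", sprintf("n%d", 1:6), "z")
  ds1 <- planted_ds(genes, "hub", sprintf("n%d", 1:6), 0.8, -0.8,
    n_met = 60, n_non = 60, seed = 41
  )
  ds2 <- planted_ds(genes, "hub", sprintf("n%d", 1:6), 0.8, -0.8,
    n_met = 60, n_non = 60, seed = 43
  )
  dc <- direction_consistency("hub", "hub", sprintf("n%d", 1:6), ds1, ds2)
  expect_equal(dc$n_shared, 6)
  expect_equal(dc$k_consistent, 6)
  expect_equal(dc$pvalue, 0.015625) # (1/2)^6
  expect_lt(dc$pvalue, 0.05)

  # dataset2 an exact copy, same hub: consistency is automatic
  self <- direction_consistency("hub", "hub", sprintf("n%d", 1:6), ds1, ds1)
  expect_equal(self$k_consistent, self$n_shared)

  # fully inconsistent: flip the group correlations in dataset 2
  ds2_flip <- planted_ds(genes, "hub", sprintf("n%d", 1:6), -0.8, 0.8,
    n_met = 60, n_non = 60, seed = 43
  )
  flip <- direction_consistency("hub", "hub", sprintf("n%d", 1:6), ds1, ds2_flip)
  expect_equal(flip$k_consistent, 0)
  expect_equal(flip$pvalue, 1)
})

test_that("POT-e reduces to POT when the restriction is vacuous or disabled", {
  sc <- synthetic_scenario(
    n_nodes = 80, n_planted = 4, hub_degree = 5,
    shared_neighbourhood_fraction = 1, n_met = 40, n_non = 40, seed = 51
  )
  net <- make_network(sc)
  ds <- make_expression(sc, net)
  p <- planted_hubs(net)

  pot <- pot_score(p$hubs1, p$hubs2, net, N = 500)
  pote <- pot_e_score(p$hubs1, p$hubs2, net, N = 500,
    ds1 = ds$ds1, ds2 = ds$ds2
  )
  # directions planted consistent and 5 shared neighbours per pair suffice
  expect_equal(pote$POT, pot$POT)

  # alpha_dir = 1 disables the restriction exactly
  pote1 <- pot_e_score(p$hubs1, p$hubs2, net, N = 500,
    ds1 = ds$ds1, ds2 = ds$ds2, alpha_dir = 1
  )
  expect_equal(pote1$POT, pot$POT)
  expect_equal(pote1$T12, pot$T12)
  expect_equal(pote1$T21, pot$T21)
})

test_that("sign-scrambling between datasets pushes POT-e back toward PO", {
  sc <- synthetic_scenario(
    n_nodes = 80, n_planted = 4, hub_degree = 5,
    shared_neighbourhood_fraction = 1, n_met = 40, n_non = 40, seed = 51,
    scramble_directions = TRUE
  )
  net <- make_network(sc)
  ds <- make_expression(sc, net)
  p <- planted_hubs(net)
  pot <- pot_score(p$hubs1, p$hubs2, net, N = 500)
  pote <- pot_e_score(p$hubs1, p$hubs2, net, N = 500,
    ds1 = ds$ds1, ds2 = ds$ds2
  )
  expect_lt(pote$POT, pot$POT)
  expect_equal(pote$POT, pote$PO) # every direction test fails
})

test_that("score ordering PO <= POT-e <= POT holds on random fixtures", {
  net <- er_net(80, 240, seed = 61)
  genes <- igraph::V(net)$name
  for (s in 1:5) {
    set.seed(s)
    l1 <- sample(genes, 8)
    l2 <- sample(genes, 10)
    ds1 <- noise_ds(genes, n_met = 10, n_non = 12, seed = s)
    ds2 <- noise_ds(genes, n_met = 10, n_non = 12, seed = s + 100)
    po <- po_score(l1, l2)$PO
    pot <- pot_score(l1, l2, net, N = 80)$POT
    pote <- pot_e_score(l1, l2, net, N = 80, ds1 = ds1, ds2 = ds2)$POT
    expect_lte(po, pote)
    expect_lte(pote, pot)
    expect_gte(po, 0)
    expect_lte(pot, 1)
  }
})
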