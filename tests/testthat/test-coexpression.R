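test_that("pearson_cc matches the product-moment formula and its edge cases", {
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_cc(c(1, 2, 3), c(3, 2, 1)), -1.0)

  # independent textbook-formula computation
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 10)
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cc(x, y), byhand, tolerance = 1e-12)

  expect_error(pearson_cc(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_cc(1:3, 1:4), "equal length")
  expect_error(pearson_cc(c(1, 1, 1), 1:3), "zero variance")
})

test_that("hub statistic is zero when both groups share identical data", {
  vals <- matrix(
    rep(cbind(c(1, 2, 5), c(2, 1, 3), c(4, 4, 1)), 2),
    nrow = 3, dimnames = list(c("h", "p1", "p2"), sprintf("s%d", 1:6))
  )
  ds <- expression_dataset(vals, rep(c("metastatic", "non-metastatic"), each = 3))
  expect_equal(hub_coexpression_stat(ds, "h", c("p1", "p2")), 0)
})

test_that("a perfect correlation flip attains the maximal statistic of 2", {
  h <- c(1, 2, 3, 4, 1, 2, 3, 4)
  vals <- rbind(h = h, p = c(1, 2, 3, 4, -1, -2, -3, -4))
  colnames(vals) <- sprintf("s%d", 1:8)
  ds <- expression_dataset(vals, rep(c("metastatic", "non-metastatic"), each = 4))
  expect_equal(hub_coexpression_stat(ds, "h", "p"), 2)
})

test_that("the statistic recovers a planted +0.8/-0.8 correlation flip", {
  genes <- c("h", sprintf("p%d", 1:5))
  ds <- planted_ds(genes, "h", sprintf("p%d", 1:5),
    rho_met = 0.8, rho_non = -0.8, n_met = 200, n_non = 200, seed = 42
  )
  expect_equal(hub_coexpression_stat(ds, "h", sprintf("p%d", 1:5)),
    1.6, tolerance = 0.1 / 1.6
  )
})

test_that("the statistic is invariant to swapping the group labels", {
  genes <- c("h", "p1", "p2", "p3")
  ds <- planted_ds(genes, "h", c("p1", "p2"), 0.6, -0.3,
    n_met = 20, n_non = 30, seed = 9
  )
  flipped <- expression_dataset(ds$values, ds$labels,
    positive_class = "non-metastatic"
  )
  expect_equal(
    hub_coexpression_stat(ds, "h", c("p1", "p2")),
    hub_coexpression_stat(flipped, "h", c("p1", "p2"))
  )
})

test_that("zero-variance partners are skipped, and all-skipped is an error", {
  set.seed(1)
  vals <- rbind(
    h = rnorm(10), good = rnorm(10), flat = rep(2, 10)
  )
  colnames(vals) <- sprintf("s%d", 1:10)
  ds <- expression_dataset(vals, rep(c("metastatic", "non-metastatic"), each = 5))
  expect_message(
    s <- hub_coexpression_stat(ds, "h", c("good", "flat")),
    "skipped 1 zero-variance"
  )
  expect_equal(s, hub_coexpression_stat(ds, "h", "good", quiet = TRUE))
  expect_error(
    hub_coexpression_stat(ds, "h", "flat", quiet = TRUE),
    "zero within-group variance"
  )
})

test_that("a dominant observed statistic gets the add-one minimum p-value", {
  # perfect flip: no permutation can reach the observed statistic of 2
  h <- rnorm(30)
  vals <- rbind(h = h, p = c(h[1:15], -h[16:30]))
  colnames(vals) <- sprintf("s%d", 1:30)
  ds <- expression_dataset(vals, rep(c("metastatic", "non-metastatic"), each = 15))
  p <- permutation_pvalue(ds, "h", "p", n_perm = 1000, seed = 2)
  expect_equal(p, 1 / 1001)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  ds <- noise_ds(c("h", "p1", "p2"), seed = 3)
  p1 <- permutation_pvalue(ds, "h", c("p1", "p2"), n_perm = 99, seed = 11)
  p2 <- permutation_pvalue(ds, "h", c("p1", "p2"), n_perm = 99, seed = 11)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
})

test_that("null permutation p-values are approximately uniform", {
  # pure-noise scenario: every hub is null; KS check on the pooled p-values
  sc <- synthetic_scenario(
    n_nodes = 120, n_planted = 0, n_met = 20, n_non = 25, seed = 5
  )
  net <- make_network(sc)
  ds <- make_expression(sc, net)$ds1
  tab <- select_signature_hubs(ds, net, n_perm = 199, seed = 17)
  expect_true(all(tab$pvalue > 0 & tab$pvalue <= 1))
  ks <- suppressWarnings(stats::ks.test(tab$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signature hub selection recovers planted hubs and respects alpha", {
  sc <- synthetic_scenario(
    n_nodes = 100, n_planted = 5, hub_degree = 5, n_met = 50, n_non = 50,
    seed = 21
  )
  net <- make_network(sc)
  ds <- make_expression(sc, net)$ds1
  tab <- select_signature_hubs(ds, net, alpha = 0.01, n_perm = 199, seed = 23)
  planted <- planted_hubs(net)$hubs1
  expect_gte(sum(planted %in% as_hub_ids(tab)), 4)

  # alpha = 0 selects nothing (p-values are strictly positive)
  tab0 <- select_signature_hubs(ds, net, alpha = 0, n_perm = 19, seed = 23)
  expect_equal(sum(tab0$selected), 0)

  # one row per hub of the network, selected <=> p < alpha
  expect_equal(nrow(tab), nrow(get_hubs(net)))
  expect_equal(tab$selected, tab$pvalue < 0.01)
})

test_that("p-values are invariant to relabeling the two phenotype classes", {
  genes <- c("h", "p1", "p2", "p3")
  ds <- planted_ds(genes, "h", c("p1", "p2", "p3"), 0.5, -0.5,
    n_met = 15, n_non = 20, seed = 31
  )
  flipped <- expression_dataset(ds$values, ds$labels,
    positive_class = "non-metastatic"
  )
  p_a <- permutation_pvalue(ds, "h", c("p1", "p2", "p3"), n_perm = 99, seed = 7)
  p_b <- permutation_pvalue(flipped, "h", c("p1", "p2", "p3"), n_perm = 99, seed = 7)
  expect_identical(p_a, p_b)
})
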