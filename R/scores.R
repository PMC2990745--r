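## Reproducibility scores between two hub lists.
##
## PO  — percentage of overlap: directional fractions k/L1, k/L2 of exactly
##       shared hubs, averaged.
## POT — percentage of overlap based on topology: a hub outside the exact
##       overlap also counts as reproduced when its interaction neighbourhood
##       overlaps, hypergeometrically significantly after FDR control, the
##       neighbourhood of at least one hub in the other list:
##       POT12 = (k + T12)/L1, POT21 = (k + T21)/L2, POT = mean of the two.
## POT-e — POT with a co-expression restriction: the neighbourhood-overlap
##       partner must additionally show binomially significant same-direction
##       correlation changes over the shared neighbours across the datasets.
## None of the scores is length-normalized.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= g)` where `X` counts shared neighbours between two proteins with
#' `n` and `m` neighbours in a background of `N` proteins (those with both
#' interaction and expression data). Computed in log space via
#' [stats::phyper()], numerically stable for `N` up to at least `1e5`.
#'
#' @param g Observed shared count, `0 <= g <= min(n, m)`.
#' @param n,m Neighbour counts of the two proteins, each `<= N`.
#' @param N Background population size.
#' @return Probability in `[0, 1]`; `g = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(2, 3, 3, 10) # 22/120
#' @export
hypergeom_upper_tail <- function(g, n, m, N) {
  if (any(g < 0) || any(n < 0) || any(m < 0) || any(N < 0)) {
    abort("all arguments must be non-negative")
  }
  if (any(g > pmin(n, m)) || any(n > N) || any(m > N)) {
    abort("need 0 <= g <= min(n, m) <= N")
  }
  phyper(g - 1, n, N - n, m, lower.tail = FALSE)
}

#' Upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`; the direction-consistency test uses
#' this with `p = 0.5` (consistent by coin flip) over shared neighbours.
#'
#' @param k Observed success count, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Success probability in `(0, 1)`.
#' @return Probability in `[0, 1]`; `k = 0` gives exactly 1.
#' @export
binom_upper_tail <- function(k, n, p = 0.5) {
  if (any(k < 0) || any(k > n)) abort("need 0 <= k <= n")
  if (any(p <= 0) || any(p >= 1)) abort("need 0 < p < 1")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

.new_score_report <- function(k, L1, L2, T12 = NA_integer_, T21 = NA_integer_,
                              variant = "plain", tests = NULL) {
  rep <- list(
    k = as.integer(k), L1 = as.integer(L1), L2 = as.integer(L2),
    T12 = T12, T21 = T21,
    PO12 = k / L1, PO21 = k / L2, PO = (k / L1 + k / L2) / 2,
    POT12 = if (is.na(T12)) NA_real_ else (k + T12) / L1,
    POT21 = if (is.na(T21)) NA_real_ else (k + T21) / L2,
    variant = variant
  )
  rep$POT <- if (is.na(T12)) NA_real_ else (rep$POT12 + rep$POT21) / 2
  structure(rep, tests = tests, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "-" else sprintf("%.1f%%", 100 * v)
  cat(sprintf(
    "<score_report: %s> k=%d L1=%d L2=%d\n  PO  = %s (%s / %s)\n",
    x$variant, x$k, x$L1, x$L2, pct(x$PO), pct(x$PO12), pct(x$PO21)
  ))
  if (!is.na(x$POT)) {
    lab <- if (x$variant == "coexpression_restricted") "POT-e" else "POT"
    cat(sprintf(
      "  %s = %s (%s / %s), T12=%d T21=%d\n",
      lab, pct(x$POT), pct(x$POT12), pct(x$POT21), x$T12, x$T21
    ))
  }
  invisible(x)
}

#' PO score from overlap counts
#'
#' Directional overlap fractions `k/L1` and `k/L2` and their average, from
#' the counts alone.
#'
#' @param k Number of hubs shared by the two lists.
#' @param L1,L2 List lengths.
#' @return A `score_report` with the PO fields populated.
#' @export
po_from_counts <- function(k, L1, L2) {
  stopifnot(k >= 0, L1 >= 1, L2 >= 1, k <= min(L1, L2))
  .new_score_report(k, L1, L2)
}

#' POT score from overlap and topology counts
#'
#' `POT12 = (k + T12)/L1`, `POT21 = (k + T21)/L2`, averaged. `T12`/`T21`
#' count list-1/list-2 hubs outside the exact overlap whose neighbourhoods
#' significantly overlap some hub of the other list, so each directional
#' score is bounded by 1.
#'
#' @inheritParams po_from_counts
#' @param T12,T21 Topology-reproduced hub counts (outside the exact overlap).
#' @return A `score_report` with PO and POT fields populated.
#' @export
pot_from_counts <- function(k, T12, T21, L1, L2) {
  stopifnot(
    k >= 0, T12 >= 0, T21 >= 0,
    k + T12 <= L1, k + T21 <= L2
  )
  .new_score_report(k, L1, L2, as.integer(T12), as.integer(T21))
}

#' Protein-level overlap (PO) score of two hub lists
#'
#' @param list1,list2 Hub lists (character vectors, `hub_list` tibbles or
#'   `signature_hub_table`s, in which case the selected hubs are used).
#' @return A `score_report` with the PO fields populated.
#' @export
po_score <- function(list1, list2) {
  h1 <- as_hub_ids(list1)
  h2 <- as_hub_ids(list2)
  if (length(h1) == 0 || length(h2) == 0) abort("hub lists must be non-empty")
  .new_score_report(length(intersect(h1, h2)), length(h1), length(h2))
}

#' Pairwise neighbourhood-overlap tests between two hub lists
#'
#' For every (hub1, hub2) pair, tests whether the two interaction
#' neighbourhoods share more proteins than expected by chance in a
#' background of `N` proteins (hypergeometric upper tail), then applies
#' Benjamini-Hochberg FDR control across all `L1 x L2` tests.
#'
#' @param list1,list2 Hub lists (see [po_score()]).
#' @param net PPI network containing all hubs (restricted to measured genes).
#' @param N Background population size: proteins with both interaction and
#'   expression data. Defaults to the node count of `net`.
#' @param fdr FDR threshold (default 0.05).
#' @return Tibble with columns `hub1`, `hub2`, `n`, `m`, `g`, `pvalue`,
#'   `p_adjusted`, `significant`; pairs sharing no neighbours have
#'   `pvalue = 1` and are never significant.
#' @export
neighbour_overlap_matrix <- function(list1, list2, net, N = NULL, fdr = 0.05) {
  net <- as_ppi_network(net, quiet = TRUE)
  h1 <- as_hub_ids(list1)
  h2 <- as_hub_ids(list2)
  missing <- setdiff(union(h1, h2), igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(sprintf("hub(s) not in network: %s", paste(missing, collapse = ", ")))
  }
  N <- N %||% igraph::vcount(net)
  if (N < igraph::vcount(net)) {
    abort("background N cannot be smaller than the (restricted) network")
  }
  nbs <- .neighbour_sets(net, union(h1, h2))
  grid <- tidyr::expand_grid(hub1 = h1, hub2 = h2)
  out <- grid |>
    dplyr::mutate(
      n = lengths(nbs[.data$hub1]),
      m = lengths(nbs[.data$hub2]),
      g = purrr::map2_int(
        .data$hub1, .data$hub2,
        function(a, b) length(intersect(nbs[[a]], nbs[[b]]))
      ),
      pvalue = hypergeom_upper_tail(.data$g, .data$n, .data$m, N),
      p_adjusted = p.adjust(.data$pvalue, method = "BH"),
      significant = .data$p_adjusted <= fdr
    )
  attr(out, "N") <- N
  attr(out, "fdr") <- fdr
  out
}

.pot_from_tests <- function(h1, h2, tests, variant, keep) {
  shared <- intersect(h1, h2)
  kept <- tests[keep, , drop = FALSE]
  T12 <- length(setdiff(unique(kept$hub1), shared))
  T21 <- length(setdiff(unique(kept$hub2), shared))
  .new_score_report(length(shared), length(h1), length(h2),
    T12 = T12, T21 = T21, variant = variant, tests = tests
  )
}

#' Topology-level overlap (POT) score of two hub lists
#'
#' Extends PO so that a hub outside the exact overlap still counts as
#' reproduced when its neighbourhood significantly overlaps (hypergeometric
#' test, BH FDR across all pairs) the neighbourhood of at least one hub in
#' the other list. Always `POT >= PO`, and each directional score is `<= 1`.
#'
#' @inheritParams neighbour_overlap_matrix
#' @return A `score_report` (variant `"plain"`) carrying the pairwise test
#'   table in `attr(, "tests")`.
#' @export
pot_score <- function(list1, list2, net, N = NULL, fdr = 0.05) {
  h1 <- as_hub_ids(list1)
  h2 <- as_hub_ids(list2)
  if (length(h1) == 0 || length(h2) == 0) abort("hub lists must be non-empty")
  tests <- neighbour_overlap_matrix(h1, h2, net, N = N, fdr = fdr)
  .pot_from_tests(h1, h2, tests, "plain", tests$significant)
}

#' Direction consistency of correlation changes over shared neighbours
#'
#' For each neighbour shared by `hub1` (evaluated in `ds1`) and `hub2`
#' (evaluated in `ds2`), the correlation-change direction is the sign of
#' PCC(hub, neighbour | positive class) minus PCC(hub, neighbour | negative
#' class). A neighbour is consistent when the two hubs' directions are equal
#' and nonzero. The count of consistent neighbours is tested against a
#' binomial upper tail with success probability `p` (default 0.5).
#'
#' Shared neighbours with zero within-group variance in either dataset are
#' excluded from the trial count (with a message).
#'
#' @param hub1,hub2 Hub gene identifiers.
#' @param shared Character vector of shared neighbour genes, measured in
#'   both datasets.
#' @param ds1,ds2 The two `expression_dataset`s.
#' @param p Bernoulli success probability (default 0.5).
#' @param quiet Suppress the excluded-neighbour message.
#' @return Object of class `direction_consistency`: a list with `hub1`,
#'   `hub2`, `n_shared`, `k_consistent`, `p_bernoulli`, `pvalue`. Zero
#'   usable shared neighbours give `pvalue = 1`.
#' @export
direction_consistency <- function(hub1, hub2, shared, ds1, ds2, p = 0.5,
                                  quiet = FALSE) {
  stopifnot(inherits(ds1, "expression_dataset"), inherits(ds2, "expression_dataset"))
  shared <- setdiff(as.character(shared), c(hub1, hub2))
  dirs <- function(ds, hub) {
    d <- .hub_xy(ds, hub, shared)
    g1 <- .positive_mask(ds)
    sign(.group_pcc(d$x, d$Yt, g1) - .group_pcc(d$x, d$Yt, !g1))
  }
  if (length(shared) == 0) {
    d1 <- d2 <- numeric(0)
  } else {
    missing <- setdiff(shared, intersect(rownames(ds1$values), rownames(ds2$values)))
    if (length(missing) > 0) {
      abort(sprintf(
        "shared neighbour(s) not measured in both datasets: %s",
        paste(missing, collapse = ", ")
      ))
    }
    d1 <- dirs(ds1, hub1)
    d2 <- dirs(ds2, hub2)
  }
  usable <- is.finite(d1) & is.finite(d2)
  if (!quiet && any(!usable)) {
    inform(sprintf(
      "direction test %s/%s: excluded %d zero-variance neighbour(s)",
      hub1, hub2, sum(!usable)
    ))
  }
  n <- sum(usable)
  k <- sum(d1[usable] == d2[usable] & d1[usable] != 0)
  structure(
    list(
      hub1 = hub1, hub2 = hub2,
      n_shared = n, k_consistent = k, p_bernoulli = p,
      pvalue = if (n == 0) 1 else binom_upper_tail(k, n, p)
    ),
    class = "direction_consistency"
  )
}

#' @export
print.direction_consistency <- function(x, ...) {
  cat(sprintf(
    "<direction_consistency> %s vs %s: %d/%d consistent, P(X >= k | n, p=%.2g) = %.4g\n",
    x$hub1, x$hub2, x$k_consistent, x$n_shared, x$p_bernoulli, x$pvalue
  ))
  invisible(x)
}

#' Co-expression-restricted POT (POT-e) score
#'
#' Identical to [pot_score()] except that a neighbourhood-overlap partner
#' pair only counts toward `T12`/`T21` when it passes both the FDR
#' neighbourhood-overlap test and the direction-consistency test
#' (`pvalue < alpha_dir`) over the pair's shared neighbours across the two
#' datasets. Consequently `PO <= POT-e <= POT` on every input, and
#' `alpha_dir = 1` disables the restriction, recovering POT exactly.
#'
#' @inheritParams pot_score
#' @param ds1,ds2 The two `expression_dataset`s (list1 hubs are evaluated in
#'   `ds1`, list2 hubs in `ds2`).
#' @param alpha_dir Direction-consistency significance level (default 0.05).
#' @param p_dir Bernoulli success probability for the direction test.
#' @return A `score_report` (variant `"coexpression_restricted"`); the test
#'   table in `attr(, "tests")` gains `dir_pvalue` and `kept` columns.
#' @export
pot_e_score <- function(list1, list2, net, N = NULL, ds1, ds2,
                        fdr = 0.05, alpha_dir = 0.05, p_dir = 0.5) {
  net <- as_ppi_network(net, quiet = TRUE)
  h1 <- as_hub_ids(list1)
  h2 <- as_hub_ids(list2)
  if (length(h1) == 0 || length(h2) == 0) abort("hub lists must be non-empty")
  tests <- neighbour_overlap_matrix(h1, h2, net, N = N, fdr = fdr)
  nbs <- .neighbour_sets(net, union(h1, h2))
  both_measured <- intersect(rownames(ds1$values), rownames(ds2$values))
  dir_p <- rep(NA_real_, nrow(tests))
  idx <- which(tests$significant)
  for (i in idx) {
    sh <- intersect(
      intersect(nbs[[tests$hub1[i]]], nbs[[tests$hub2[i]]]),
      both_measured
    )
    dir_p[i] <- direction_consistency(
      tests$hub1[i], tests$hub2[i], sh, ds1, ds2,
      p = p_dir, quiet = TRUE
    )$pvalue
  }
  keep <- tests$significant &
    (alpha_dir >= 1 | (!is.na(dir_p) & dir_p < alpha_dir))
  tests$dir_pvalue <- dir_p
  tests$kept <- keep
  .pot_from_tests(h1, h2, tests, "coexpression_restricted", keep)
}
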