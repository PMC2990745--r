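## Per-hub differential co-expression statistic and permutation selection.
##
## For a hub h with partners P, the statistic is
##   | mean_{p in P} PCC(h, p | group1)  -  mean_{p in P} PCC(h, p | group2) |,
## i.e. the absolute difference of the per-group average Pearson correlation
## between the hub and its interaction partners. Significance comes from
## permuting the phenotype labels (group sizes preserved) and recomputing.

#' Pearson correlation coefficient
#'
#' Thin validating wrapper around [stats::cor()]: requires equal lengths of
#' at least 3 and non-degenerate variance in both vectors.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  cor(x, y)
}

## Correlations of hub vector x with each column of Yt (samples x partners)
## within the sample mask g. Zero-variance columns yield NA (warning hidden).
.group_pcc <- function(x, Yt, g) {
  suppressWarnings(as.vector(cor(x[g], Yt[g, , drop = FALSE])))
}

## stat for one label assignment; NA when no partner is usable
.stat_for_mask <- function(x, Yt, g1) {
  c1 <- .group_pcc(x, Yt, g1)
  c2 <- .group_pcc(x, Yt, !g1)
  keep <- is.finite(c1) & is.finite(c2)
  if (!any(keep)) return(NA_real_)
  abs(mean(c1[keep]) - mean(c2[keep]))
}

.hub_xy <- function(ds, hub, partners) {
  partners <- setdiff(as.character(partners), hub)
  missing <- setdiff(c(hub, partners), rownames(ds$values))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) not in dataset: %s", paste(missing, collapse = ", ")))
  }
  if (length(partners) == 0) abort("hub has no partners to correlate with")
  list(
    x = ds$values[hub, ],
    Yt = t(ds$values[partners, , drop = FALSE]),
    partners = partners
  )
}

#' Hub co-expression-change statistic
#'
#' Absolute difference, between the two phenotype groups, of the average
#' Pearson correlation between a hub and its interaction partners. Bounded
#' by 2 (difference of two means of correlations). Partners with zero
#' variance within either group are skipped with a message; if every partner
#' is skipped the statistic is undefined and an error is raised.
#'
#' @param ds An `expression_dataset`.
#' @param hub Hub gene identifier.
#' @param partners Character vector of partner gene identifiers.
#' @param quiet Suppress the skipped-partner message.
#' @return The statistic, a non-negative real `<= 2`.
#' @export
hub_coexpression_stat <- function(ds, hub, partners, quiet = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  d <- .hub_xy(ds, hub, partners)
  g1 <- .positive_mask(ds)
  c1 <- .group_pcc(d$x, d$Yt, g1)
  c2 <- .group_pcc(d$x, d$Yt, !g1)
  keep <- is.finite(c1) & is.finite(c2)
  if (!any(keep)) {
    abort(sprintf("all partners of hub '%s' have zero within-group variance", hub))
  }
  if (!quiet && any(!keep)) {
    inform(sprintf(
      "hub '%s': skipped %d zero-variance partner(s)", hub, sum(!keep)
    ))
  }
  abs(mean(c1[keep]) - mean(c2[keep]))
}

## Shared core of permutation_pvalue and select_signature_hubs. Permuted
## statistics that are undefined (all partners degenerate) count as >= the
## observed value, which is conservative.
.perm_test_hub <- function(x, Yt, g1, n_perm, seed) {
  obs <- .stat_for_mask(x, Yt, g1)
  if (is.na(obs)) return(c(stat = NA_real_, pvalue = NA_real_))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(g1)
  n1 <- sum(g1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- logical(n)
    g[sample.int(n, n1)] <- TRUE
    s <- .stat_for_mask(x, Yt, g)
    if (is.na(s) || s >= obs) hits <- hits + 1L
  }
  c(stat = obs, pvalue = (1 + hits) / (n_perm + 1))
}

#' Permutation p-value for a hub's co-expression change
#'
#' Shuffles the phenotype labels `n_perm` times (group sizes preserved) and
#' reports the add-one empirical p-value
#' `(1 + #\{permuted stat >= observed\}) / (n_perm + 1)`, which is never zero.
#'
#' @inheritParams hub_coexpression_stat
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(ds, hub, partners, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), n_perm >= 1)
  ## observed stat computed via the public path so degenerate hubs error out
  hub_coexpression_stat(ds, hub, partners, quiet = TRUE)
  d <- .hub_xy(ds, hub, partners)
  unname(.perm_test_hub(d$x, d$Yt, .positive_mask(ds), n_perm, seed)["pvalue"])
}

#' Select signature hubs by permutation test
#'
#' Scores every hub of the network (degree >= `min_degree`) with the
#' co-expression-change statistic and a label-permutation p-value, and flags
#' the hubs with `p < alpha` as signature hubs. No multiple-testing
#' adjustment is applied at this stage; the downstream reproducibility
#' scores carry their own FDR control.
#'
#' Sub-seeds for the per-hub permutation tests are streamed from the master
#' `seed` in lexicographic hub order, so results do not depend on the order
#' in which hubs are visited.
#'
#' @param ds An `expression_dataset`; the network must already be restricted
#'   to its measured genes.
#' @param net PPI network restricted to the measured genes.
#' @param alpha Selection threshold on the permutation p-value (default 0.01).
#' @param min_degree Hub degree cut-off (default 3).
#' @param n_perm Label permutations per hub (default 1000).
#' @param seed Master integer seed.
#' @return A tibble of class `signature_hub_table` with columns `hub`,
#'   `degree`, `stat`, `pvalue`, `selected`.
#' @export
select_signature_hubs <- function(ds, net, alpha = 0.01, min_degree = 3,
                                  n_perm = 1000, seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  net <- as_ppi_network(net, quiet = TRUE)
  unmeasured <- setdiff(igraph::V(net)$name, rownames(ds$values))
  if (length(unmeasured) > 0) {
    abort(sprintf(
      "network contains %d gene(s) without expression data; run restrict_to_measured() first",
      length(unmeasured)
    ))
  }
  hubs <- get_hubs(net, min_degree = min_degree)
  seeds <- derive_seeds(seed, nrow(hubs))
  nbs <- .neighbour_sets(net, hubs$hub)
  g1 <- .positive_mask(ds)
  n_failed <- 0L
  res <- purrr::map2(hubs$hub, seq_len(nrow(hubs)), function(h, i) {
    d <- .hub_xy(ds, h, nbs[[h]])
    out <- .perm_test_hub(d$x, d$Yt, g1, n_perm, seeds[i])
    if (is.na(out["stat"])) n_failed <<- n_failed + 1L
    out
  })
  if (n_failed > 0) {
    warn(sprintf("%d hub(s) had no usable partner and were left unscored", n_failed))
  }
  out <- tibble::tibble(
    hub = hubs$hub,
    degree = hubs$degree,
    stat = purrr::map_dbl(res, "stat"),
    pvalue = purrr::map_dbl(res, "pvalue"),
    selected = !is.na(pvalue) & pvalue < alpha
  )
  class(out) <- c("signature_hub_table", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "min_degree") <- min_degree
  attr(out, "n_perm") <- n_perm
  attr(out, "dataset") <- ds$name
  out
}
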