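## broom-style tidiers: tidy() returns the per-unit table, glance() a
## one-row summary, for each result class.

#' Tidy the per-hub table (plain tibble).
#' @param x A `signature_hub_table`.
#' @param ... Unused.
#' @export
tidy.signature_hub_table <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  out
}

#' One-row summary of a hub selection run.
#' @export
glance.signature_hub_table <- function(x, ...) {
  tibble::tibble(
    n_hubs = nrow(x),
    n_selected = sum(x$selected, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    min_degree = attr(x, "min_degree"),
    n_perm = attr(x, "n_perm")
  )
}

#' Tidy a score report into one row per direction.
#' @param x A `score_report`.
#' @param ... Unused.
#' @export
tidy.score_report <- function(x, ...) {
  tibble::tibble(
    direction = c("1->2", "2->1"),
    length = c(x$L1, x$L2),
    k = x$k,
    T = c(x$T12, x$T21),
    po = c(x$PO12, x$PO21),
    pot = c(x$POT12, x$POT21),
    variant = x$variant
  )
}

#' One-row summary of a score report.
#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(
    k = x$k, L1 = x$L1, L2 = x$L2, T12 = x$T12, T21 = x$T21,
    PO = x$PO, POT = x$POT, variant = x$variant
  )
}

#' Tidy a null distribution (one row per sample).
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(
    replicate = seq_along(x$samples),
    score = x$samples,
    scheme = x$scheme
  )
}

#' One-row summary of a null distribution.
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    n_rep = length(x$samples),
    mean = x$mean,
    observed = x$observed,
    empirical_p = x$empirical_p
  )
}

#' Tidy the enrichment table (plain tibble).
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row summary of an enrichment run.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$qsignificant),
    n_pathways_hit = length(significant_pathways(x)),
    fdr = attr(x, "fdr"),
    background_size = attr(x, "background_size")
  )
}

#' Tidy a direction-consistency test.
#' @param x A `direction_consistency`.
#' @param ... Unused.
#' @export
tidy.direction_consistency <- function(x, ...) {
  tibble::tibble(
    hub1 = x$hub1, hub2 = x$hub2,
    n_shared = x$n_shared, k_consistent = x$k_consistent,
    p_bernoulli = x$p_bernoulli, pvalue = x$pvalue
  )
}
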