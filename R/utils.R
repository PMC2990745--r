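## Seed streaming: every randomized stage consumes named sub-seeds derived
## from one master seed, so a pipeline run is reproducible end to end and
## independent stages do not share RNG state.

#' Derive a stream of reproducible sub-seeds from a master seed
#'
#' Draws `n` integer seeds deterministically from `seed`. Used internally so
#' that per-hub permutation tests and per-replicate null-model runs are
#' reproducible and order-independent.
#'
#' @param seed Master integer seed, or `NULL` to draw one from the session RNG.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, all in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(n), n >= 0)
  if (n == 0) return(integer(0))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n, replace = FALSE)
}

## sample() misbehaves on a length-1 pool (samples 1:x); this does not.
resample <- function(x, size, prob = NULL) {
  if (size == 0L) return(x[0])
  if (length(x) == 1L) {
    if (size > 1L) abort("cannot sample more elements than the pool holds")
    return(x)
  }
  sample(x, size, replace = FALSE, prob = prob)
}

#' Extract hub identifiers from a hub list or character vector
#'
#' Accepts either the tibble returned by [get_hubs()] / [select_signature_hubs()]
#' (uses the `hub` column; for signature-hub tables only the selected rows)
#' or a plain character vector.
#'
#' @param x Hub list tibble or character vector.
#' @return Character vector of gene identifiers, duplicates removed.
#' @export
as_hub_ids <- function(x) {
  if (inherits(x, "signature_hub_table")) {
    return(unique(x$hub[which(x$selected)]))
  }
  if (is.data.frame(x)) {
    if (!"hub" %in% names(x)) abort("hub list data frame needs a `hub` column")
    return(unique(as.character(x$hub)))
  }
  unique(as.character(x))
}

#' Empirical p-value with the add-one convention
#'
#' `p = (1 + #\{null samples >= observed\}) / (n + 1)`, so `p` is never zero
#' and an observed value exceeding every null sample reports `1 / (n + 1)`.
#'
#' @param samples Numeric vector of null-model samples.
#' @param observed Observed score.
#' @return p-value in `(0, 1]`, or `NA` if `observed` is `NA`.
#' @export
empirical_pvalue <- function(samples, observed) {
  if (is.na(observed)) return(NA_real_)
  (1 + sum(samples >= observed)) / (length(samples) + 1)
}
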