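## Randomization null models for the topology-level reproducibility scores.
## Three schemes, each destroying one candidate explanation of a high score:
##   phenotype_permutation — disease relevance (labels shuffled, correlation
##     structure kept; the whole hub-selection pipeline is re-run);
##   random_lists — network topology (random protein lists of the same
##     lengths, scored on the real network);
##   rewired_network — hub degrees (degree-matched lists scored on
##     degree-preserving rewired networks).

new_null_distribution <- function(scheme, samples, observed) {
  structure(
    list(
      scheme = scheme,
      samples = as.numeric(samples),
      observed = observed,
      mean = mean(samples),
      empirical_p = empirical_pvalue(samples, observed)
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %s> %d replicates, mean = %.4g",
    x$scheme, length(x$samples), x$mean
  ))
  if (!is.na(x$observed)) {
    cat(sprintf(", observed = %.4g, empirical p = %.4g", x$observed, x$empirical_p))
    if (x$empirical_p <= 1 / (length(x$samples) + 1)) {
      cat(sprintf(" (no null sample reached the observed value: p < 1/%d)",
                  length(x$samples) + 1))
    }
  }
  cat("\n")
  invisible(x)
}

.score_pair <- function(l1, l2, net, N, ds1 = NULL, ds2 = NULL,
                        score = "POT", fdr = 0.05, alpha_dir = 0.05) {
  if (length(l1) == 0 || length(l2) == 0) return(NA_real_)
  rep <- if (score == "POT-e") {
    pot_e_score(l1, l2, net, N = N, ds1 = ds1, ds2 = ds2,
                fdr = fdr, alpha_dir = alpha_dir)
  } else {
    pot_score(l1, l2, net, N = N, fdr = fdr)
  }
  rep$POT
}

#' Phenotype-permutation null for POT / POT-e
#'
#' Each replicate reassigns phenotype labels at random within each dataset
#' (group sizes preserved, correlation structure intact), re-runs signature
#' hub selection in both datasets, and scores the resulting lists. A
#' replicate in which either list comes out empty contributes a score of 0
#' (with a message). The observed score is computed from the unpermuted
#' labels with the same settings.
#'
#' @param ds1,ds2 The two `expression_dataset`s.
#' @param net PPI network restricted to the genes measured in both datasets.
#' @param n_rep Number of replicates.
#' @param seed Master integer seed.
#' @param score `"POT"` or `"POT-e"`.
#' @param N Background population size (default: node count of `net`).
#' @param alpha Hub-selection threshold (default 0.01).
#' @param min_degree Hub degree cut-off.
#' @param n_perm Inner label permutations used for hub selection in each
#'   replicate (default 100; the full-pipeline default of 1000 is
#'   computationally heavy inside a null loop).
#' @param fdr Neighbourhood-overlap FDR.
#' @param alpha_dir Direction-consistency level (POT-e only).
#' @return A `null_distribution` (scheme `"phenotype_permutation"`).
#' @export
null_phenotype_permutation <- function(ds1, ds2, net, n_rep = 1000, seed = NULL,
                                       score = c("POT", "POT-e"), N = NULL,
                                       alpha = 0.01, min_degree = 3,
                                       n_perm = 100, fdr = 0.05,
                                       alpha_dir = 0.05) {
  score <- match.arg(score)
  net <- as_ppi_network(net, quiet = TRUE)
  N <- N %||% igraph::vcount(net)
  seeds <- matrix(derive_seeds(seed, 4 * (n_rep + 1)), ncol = 4)
  run_once <- function(d1, d2, s) {
    h1 <- select_signature_hubs(d1, net, alpha = alpha, min_degree = min_degree,
                                n_perm = n_perm, seed = s[1])
    h2 <- select_signature_hubs(d2, net, alpha = alpha, min_degree = min_degree,
                                n_perm = n_perm, seed = s[2])
    l1 <- as_hub_ids(h1)
    l2 <- as_hub_ids(h2)
    if (length(l1) == 0 || length(l2) == 0) {
      inform("replicate produced an empty hub list; score set to 0")
      return(0)
    }
    .score_pair(l1, l2, net, N, d1, d2, score, fdr, alpha_dir)
  }
  observed <- run_once(ds1, ds2, seeds[n_rep + 1, ])
  samples <- purrr::map_dbl(seq_len(n_rep), function(i) {
    run_once(
      permute_labels(ds1, seed = seeds[i, 3]),
      permute_labels(ds2, seed = seeds[i, 4]),
      seeds[i, ]
    )
  })
  new_null_distribution("phenotype_permutation", samples, observed)
}

#' Random-protein-list null for POT
#'
#' Each replicate draws a fresh pair of protein lists of the given lengths
#' uniformly from the network nodes (without replacement) and computes their
#' POT score on the real network, asking how much topology-level overlap two
#' arbitrary lists of these lengths accrue by chance.
#'
#' @param net PPI network.
#' @param L1,L2 List lengths matching the signature hub lists.
#' @param N Background population size.
#' @param n_rep Number of replicates.
#' @param seed Master integer seed.
#' @param fdr Neighbourhood-overlap FDR.
#' @param pool `"all"` (default) samples from every node; `"hubs_only"`
#'   restricts the pool to nodes of degree >= `min_degree`.
#' @param min_degree Hub cut-off for `pool = "hubs_only"`.
#' @param observed Observed POT score to locate in the null (optional).
#' @return A `null_distribution` (scheme `"random_lists"`).
#' @export
null_random_lists <- function(net, L1, L2, N = NULL, n_rep = 1000, seed = NULL,
                              fdr = 0.05, pool = c("all", "hubs_only"),
                              min_degree = 3, observed = NA_real_) {
  pool <- match.arg(pool)
  net <- as_ppi_network(net, quiet = TRUE)
  N <- N %||% igraph::vcount(net)
  seeds <- derive_seeds(seed, n_rep)
  samples <- purrr::map_dbl(seeds, function(s) {
    ls <- sample_random_hub_lists(net, L1, L2,
      mode = "any_protein", pool = pool, min_degree = min_degree, seed = s
    )
    .score_pair(ls$list1, ls$list2, net, N, score = "POT", fdr = fdr)
  })
  new_null_distribution("random_lists", samples, observed)
}

#' Rewired-network null for POT
#'
#' Each replicate rewires the network with degree-preserving edge swaps,
#' samples a pair of lists whose degree multisets equal those of the two
#' signature hub lists, and computes their POT score within the rewired
#' network. This asks whether the observed score is explained by the hubs'
#' high connectivity alone.
#'
#' @param net PPI network.
#' @param hubs1,hubs2 The two signature hub lists (see [po_score()]).
#' @param N Background population size.
#' @param n_rep Number of replicates.
#' @param seed Master integer seed.
#' @param fdr Neighbourhood-overlap FDR.
#' @param n_swaps_per_edge Swap attempts per edge for the rewiring.
#' @param observed Observed POT score to locate in the null (optional).
#' @return A `null_distribution` (scheme `"rewired_network"`).
#' @export
null_rewired <- function(net, hubs1, hubs2, N = NULL, n_rep = 1000, seed = NULL,
                         fdr = 0.05, n_swaps_per_edge = 10,
                         observed = NA_real_) {
  net <- as_ppi_network(net, quiet = TRUE)
  N <- N %||% igraph::vcount(net)
  deg <- igraph::degree(net)
  h1 <- as_hub_ids(hubs1)
  h2 <- as_hub_ids(hubs2)
  ref <- list(unname(deg[h1]), unname(deg[h2]))
  seeds <- matrix(derive_seeds(seed, 2 * n_rep), ncol = 2)
  samples <- purrr::map_dbl(seq_len(n_rep), function(i) {
    rnet <- rewire_preserving_degrees(net, n_swaps_per_edge, seed = seeds[i, 1])
    ls <- sample_random_hub_lists(rnet,
      mode = "degree_matched", reference_degrees = ref, seed = seeds[i, 2]
    )
    .score_pair(ls$list1, ls$list2, rnet, N, score = "POT", fdr = fdr)
  })
  new_null_distribution("rewired_network", samples, observed)
}
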