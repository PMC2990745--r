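## Synthetic study generator: a heavy-tailed interaction network with pairs
## of planted hubs whose neighbourhoods overlap by a controlled fraction,
## plus two-cohort expression data in which each planted hub's partners
## track the hub with a group-specific correlation. Dataset 1 carries the
## signal at the "A" hubs, dataset 2 at the "B" hubs, so the two recovered
## signature lists share neighbourhoods (high POT) without sharing hub
## identities (PO near 0) -- the structure the reproducibility scores are
## designed to detect.

#' Define a synthetic two-cohort scenario
#'
#' Collects all generator parameters. Defaults describe a desk-scale study:
#' a 150-node background interactome, 10 planted hub pairs of degree 6 whose
#' neighbourhoods overlap by 80%, and two cohorts of 35 metastatic / 60
#' non-metastatic samples (an imbalanced case/control split typical of
#' metastasis follow-up cohorts). Planted partners correlate with their hub
#' at `rho_met = +0.8` in the metastatic group and `rho_non = -0.8` in the
#' non-metastatic group, a strong, recoverable co-expression flip.
#'
#' @param n_nodes Background network size (>= 10).
#' @param attach_m Edges added per node by preferential attachment (also the
#'   minimum degree of every background node).
#' @param n_planted Planted hub pairs (0 for a pure-noise scenario).
#' @param hub_degree Partners per planted hub (>= 3).
#' @param shared_neighbourhood_fraction Fraction of each A-hub's partners
#'   reused by its paired B-hub, in `[0, 1]`; sets the expected
#'   topology-level overlap between the two datasets' planted lists.
#' @param n_met,n_non Samples per group in each cohort (>= 3).
#' @param rho_met,rho_non Within-group hub-partner correlation of planted
#'   partners, `|rho| < 1`.
#' @param scramble_directions If `TRUE`, dataset 2 swaps the two group
#'   correlations, destroying cross-dataset direction consistency while
#'   leaving the per-dataset signal intact (a POT-e negative control).
#' @param noise_sd `NULL` (default) calibrates partner noise so the
#'   population within-group correlation is exactly `rho` (partner =
#'   `rho * hub + sqrt(1 - rho^2) * noise`); a positive value is used as-is,
#'   attenuating the correlation to `rho / sqrt(rho^2 + noise_sd^2)`.
#' @param seed Master integer seed for the whole scenario.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_nodes = 150, attach_m = 3, n_planted = 10,
                               hub_degree = 6,
                               shared_neighbourhood_fraction = 0.8,
                               n_met = 35, n_non = 60,
                               rho_met = 0.8, rho_non = -0.8,
                               scramble_directions = FALSE,
                               noise_sd = NULL, seed = 1) {
  stopifnot(
    n_nodes >= 10, attach_m >= 1, n_planted >= 0, hub_degree >= 3,
    shared_neighbourhood_fraction >= 0, shared_neighbourhood_fraction <= 1,
    n_met >= 3, n_non >= 3,
    abs(rho_met) < 1, abs(rho_non) < 1
  )
  needed <- ceiling(n_planted * hub_degree * (2 - shared_neighbourhood_fraction))
  if (needed > n_nodes) {
    abort(sprintf(
      "planted structure needs ~%d background nodes but n_nodes = %d",
      needed, n_nodes
    ))
  }
  structure(
    list(
      n_nodes = n_nodes, attach_m = attach_m, n_planted = n_planted,
      hub_degree = hub_degree,
      shared_neighbourhood_fraction = shared_neighbourhood_fraction,
      n_met = n_met, n_non = n_non,
      rho_met = rho_met, rho_non = rho_non,
      scramble_directions = scramble_directions,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> %d background nodes (m=%d), %d planted hub pair(s) of degree %d (shared fraction %.2f)\n  cohorts: %d metastatic / %d non-metastatic; rho = %+.2f / %+.2f%s; seed %d\n",
    x$n_nodes, x$attach_m, x$n_planted, x$hub_degree,
    x$shared_neighbourhood_fraction, x$n_met, x$n_non,
    x$rho_met, x$rho_non,
    if (x$scramble_directions) " (dataset 2 scrambled)" else "", x$seed
  ))
  invisible(x)
}

## preferential attachment that guarantees degree >= m for every node:
## start from a clique on m+1 nodes, then attach each new node to m distinct
## existing nodes with probability proportional to current degree.
.pa_edges <- function(n, m) {
  stopifnot(n >= m + 1)
  deg <- integer(n)
  from <- integer(0)
  to <- integer(0)
  init <- utils::combn(seq_len(m + 1), 2)
  from <- init[1, ]
  to <- init[2, ]
  deg[seq_len(m + 1)] <- m
  for (v in seq(m + 2, length.out = n - m - 1)) {
    existing <- seq_len(v - 1)
    targets <- resample(existing, m, prob = deg[existing])
    from <- c(from, rep(v, m))
    to <- c(to, targets)
    deg[v] <- deg[v] + m
    deg[targets] <- deg[targets] + 1L
  }
  cbind(from, to)
}

#' Generate the synthetic interaction network
#'
#' Builds the preferential-attachment background (heavy-tailed degrees,
#' every node with degree >= `attach_m`) and appends the planted hub pairs:
#' each pair (A_i, B_i) consists of two new nodes wired to `hub_degree`
#' background partners, with `round(fraction * hub_degree)` partners shared
#' between A_i and B_i. Partner pools are disjoint across planted hubs
#' within each dataset. The planted assignment is stored as the graph
#' attribute `"planted"` and consumed by [make_expression()] and
#' [make_genesets()].
#'
#' @param scenario A `synthetic_scenario`.
#' @return An `igraph` PPI network with graph attribute `planted`.
#' @export
make_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  set.seed(derive_seeds(s$seed, 4)[1])
  base_names <- sprintf("g%04d", seq_len(s$n_nodes))
  el <- .pa_edges(s$n_nodes, s$attach_m)
  edges <- cbind(base_names[el[, 1]], base_names[el[, 2]])

  hubs1 <- hubs2 <- character(0)
  partners1 <- partners2 <- list()
  if (s$n_planted > 0) {
    hubs1 <- sprintf("hubA%02d", seq_len(s$n_planted))
    hubs2 <- sprintf("hubB%02d", seq_len(s$n_planted))
    n_shared <- round(s$shared_neighbourhood_fraction * s$hub_degree)
    avail <- base_names
    for (i in seq_len(s$n_planted)) {
      pa <- resample(avail, s$hub_degree)
      avail <- setdiff(avail, pa)
      fresh <- resample(avail, s$hub_degree - n_shared)
      avail <- setdiff(avail, fresh)
      pb <- c(resample(pa, n_shared), fresh)
      partners1[[i]] <- pa
      partners2[[i]] <- pb
      edges <- rbind(
        edges,
        cbind(hubs1[i], pa),
        cbind(hubs2[i], pb)
      )
    }
    names(partners1) <- hubs1
    names(partners2) <- hubs2
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::graph_attr(g, "planted") <- list(
    hubs1 = hubs1, hubs2 = hubs2,
    partners1 = partners1, partners2 = partners2
  )
  g
}

#' Planted-hub assignment of a synthetic network
#' @param net A network built by [make_network()].
#' @return List with `hubs1`, `hubs2`, `partners1`, `partners2`.
#' @export
planted_hubs <- function(net) {
  p <- igraph::graph_attr(net, "planted")
  if (is.null(p)) abort("network carries no planted-hub annotation")
  p
}

.simulate_cohort <- function(net, planted_h, planted_p, rho_met, rho_non,
                             n_met, n_non, noise_sd, name) {
  genes <- igraph::V(net)$name
  n <- n_met + n_non
  vals <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("%s_s%03d", name, seq_len(n))))
  labels <- c(rep("metastatic", n_met), rep("non-metastatic", n_non))
  mix <- function(rho, h, eps) {
    if (is.null(noise_sd)) rho * h + sqrt(1 - rho^2) * eps
    else rho * h + noise_sd * eps
  }
  met <- labels == "metastatic"
  for (h in planted_h) {
    hx <- vals[h, ]
    for (p in planted_p[[h]]) {
      eps <- vals[p, ] # the partner's own noise, reused as innovation
      vals[p, met] <- mix(rho_met, hx[met], eps[met])
      vals[p, !met] <- mix(rho_non, hx[!met], eps[!met])
    }
  }
  expression_dataset(vals, labels, positive_class = "metastatic", name = name)
}

#' Generate the paired two-cohort expression data
#'
#' Dataset 1 plants the co-expression flip at the A-hubs, dataset 2 at the
#' B-hubs; all other genes (including the other dataset's planted hubs) are
#' independent standard normal noise. Within each group a planted partner
#' is `rho * hub + sqrt(1 - rho^2) * noise`, giving a population
#' within-group Pearson correlation of exactly `rho`, so the expected hub
#' statistic is `|rho_met - rho_non|` (attenuated only by sampling noise).
#'
#' @param scenario A `synthetic_scenario`.
#' @param net The network from [make_network()].
#' @return List of two `expression_dataset`s (`ds1`, `ds2`).
#' @export
make_expression <- function(scenario, net) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  p <- planted_hubs(net)
  seeds <- derive_seeds(s$seed, 4)
  set.seed(seeds[2])
  ds1 <- .simulate_cohort(net, p$hubs1, p$partners1, s$rho_met, s$rho_non,
                          s$n_met, s$n_non, s$noise_sd, "cohort1")
  set.seed(seeds[3])
  rm2 <- if (s$scramble_directions) s$rho_non else s$rho_met
  rn2 <- if (s$scramble_directions) s$rho_met else s$rho_non
  ds2 <- .simulate_cohort(net, p$hubs2, p$partners2, rm2, rn2,
                          s$n_met, s$n_non, s$noise_sd, "cohort2")
  list(ds1 = ds1, ds2 = ds2)
}

#' Generate a pathway collection matched to the planted structure
#'
#' One pathway per planted hub pair, built as the union of the pair's
#' partner sets plus a few random background fillers, plus filler-only
#' pathways as negative controls. Background = all network nodes.
#'
#' @param scenario A `synthetic_scenario`.
#' @param net The network from [make_network()].
#' @param n_filler Random filler genes added to each planted pathway.
#' @param n_filler_sets Number of filler-only pathways.
#' @param filler_set_size Genes per filler-only pathway.
#' @return A `geneset_collection`.
#' @export
make_genesets <- function(scenario, net, n_filler = 4, n_filler_sets = 5,
                          filler_set_size = 12) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  p <- planted_hubs(net)
  set.seed(derive_seeds(s$seed, 4)[4])
  genes <- igraph::V(net)$name
  base <- setdiff(genes, c(p$hubs1, p$hubs2))
  sets <- list()
  for (i in seq_along(p$hubs1)) {
    members <- union(p$partners1[[i]], p$partners2[[i]])
    sets[[sprintf("planted_pathway_%02d", i)]] <-
      union(members, resample(setdiff(base, members), n_filler))
  }
  for (j in seq_len(n_filler_sets)) {
    sets[[sprintf("filler_pathway_%02d", j)]] <- resample(base, filler_set_size)
  }
  geneset_collection(sets, background = genes, quiet = TRUE)
}
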