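# Small graphs and expression fixtures, all built in code.

edges_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

star_net <- function(leaves = c("l1", "l2", "l3"), center = "c") {
  as_ppi_network(data.frame(from = center, to = leaves), quiet = TRUE)
}

path_net <- function() {
  as_ppi_network(edges_df("a", "b", "b", "c"), quiet = TRUE)
}

k4_net <- function() {
  as_ppi_network(edges_df(
    "a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d"
  ), quiet = TRUE)
}

triangle_net <- function() {
  as_ppi_network(edges_df("a", "b", "b", "c", "c", "a"), quiet = TRUE)
}

cycle4_net <- function() {
  as_ppi_network(edges_df("a", "b", "b", "c", "c", "d", "d", "a"), quiet = TRUE)
}

er_net <- function(n = 200, m = 600, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  g
}

# Pure-noise dataset over the given genes.
noise_ds <- function(genes, n_met = 10, n_non = 12, seed = 1, name = NULL) {
  set.seed(seed)
  n <- n_met + n_non
  vals <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  expression_dataset(
    vals, c(rep("metastatic", n_met), rep("non-metastatic", n_non)),
    name = name
  )
}

# Dataset where `partners` of `hub` have within-group population correlation
# rho_met / rho_non with the hub; all other genes are noise.
planted_ds <- function(genes, hub, partners, rho_met, rho_non,
                       n_met = 50, n_non = 50, seed = 1) {
  set.seed(seed)
  n <- n_met + n_non
  vals <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  met <- c(rep(TRUE, n_met), rep(FALSE, n_non))
  hx <- vals[hub, ]
  for (p in partners) {
    eps <- vals[p, ]
    vals[p, met] <- rho_met * hx[met] + sqrt(1 - rho_met^2) * eps[met]
    vals[p, !met] <- rho_non * hx[!met] + sqrt(1 - rho_non^2) * eps[!met]
  }
  expression_dataset(
    vals, ifelse(met, "metastatic", "non-metastatic")
  )
}

# Two disjoint hub pairs wired to identical partner neighbourhoods, plus
# filler nodes so the background N can be large: the canonical
# "PO = 0, POT = 1" topology.
twin_hub_net <- function(n_partners = 10, n_filler = 30) {
  partners <- sprintf("p%02d", seq_len(n_partners))
  el <- rbind(
    data.frame(from = "hubA", to = partners),
    data.frame(from = "hubB", to = partners)
  )
  if (n_filler > 0) {
    fill <- sprintf("f%02d", seq_len(n_filler))
    el <- rbind(el, data.frame(from = fill, to = c(fill[-1], fill[1])))
  }
  as_ppi_network(el, quiet = TRUE)
}

# Brute-force tail oracles (independent of the package implementation).
hyper_tail_enum <- function(g, n, m, N) {
  i <- seq(g, min(n, m))
  if (length(i) == 0) return(0)
  sum(choose(n, i) * choose(N - n, m - i)) / choose(N, m)
}

binom_tail_enum <- function(k, n, p) {
  i <- seq(k, n)
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}
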