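## Pathway-level consistency: hypergeometric enrichment of each hub's
## interaction neighbours in gene sets, overlap of enriched-pathway sets
## between hub lists, a rewiring null for that overlap, and an
## over-representation test of shared neighbours in special gene lists
## (e.g. curated cancer genes).

#' Construct a gene-set collection
#'
#' Restricts every set to the background universe and drops sets left empty
#' (with a message). The background defaults to the union of all set
#' members; for hub-neighbour enrichment it should be the proteins with
#' both interaction and expression data.
#'
#' @param sets Named list of character vectors (gene identifiers).
#' @param background Character vector: the gene universe.
#' @param quiet Suppress the dropped-set message.
#' @return Object of class `geneset_collection`: list with `sets` and
#'   `background`.
#' @export
geneset_collection <- function(sets, background = NULL, quiet = FALSE) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("gene sets must be named")
  }
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names")
  background <- unique(as.character(background %||% unlist(sets)))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), background))
  empty <- lengths(sets) == 0
  if (any(empty) && !quiet) {
    inform(sprintf("dropped %d gene set(s) empty after background restriction",
                   sum(empty)))
  }
  structure(
    list(sets = sets[!empty], background = background),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf(
    "<geneset_collection> %d sets (sizes %d-%d), background %d genes\n",
    length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
    length(x$background)
  ))
  invisible(x)
}

#' Pathway enrichment of hub interaction neighbours
#'
#' For every (hub, pathway) pair, tests whether the hub's interaction
#' neighbours (the hub itself excluded, restricted to the background) are
#' over-represented in the pathway by the hypergeometric upper tail, then
#' applies Benjamini-Hochberg FDR control across all tests of the run.
#' A hub with no in-background neighbour gets `pvalue = 1` on every pathway.
#'
#' @param hubs Hub list (see [po_score()]).
#' @param net PPI network.
#' @param gsc A `geneset_collection`.
#' @param fdr FDR threshold (default 0.01).
#' @return Tibble of class `enrichment_result` with columns `hub`,
#'   `pathway`, `n_neighbours`, `n_pathway`, `overlap`, `pvalue`,
#'   `p_adjusted`, `qsignificant`.
#' @export
enrich_neighbours <- function(hubs, net, gsc, fdr = 0.01) {
  stopifnot(inherits(gsc, "geneset_collection"))
  net <- as_ppi_network(net, quiet = TRUE)
  h <- as_hub_ids(hubs)
  missing <- setdiff(h, igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(sprintf("hub(s) not in network: %s", paste(missing, collapse = ", ")))
  }
  bg <- gsc$background
  N <- length(bg)
  nbs <- .neighbour_sets(net, h)
  nbs <- lapply(h, function(x) setdiff(intersect(nbs[[x]], bg), x))
  names(nbs) <- h
  out <- tidyr::expand_grid(hub = h, pathway = names(gsc$sets)) |>
    dplyr::mutate(
      n_neighbours = lengths(nbs[.data$hub]),
      n_pathway = lengths(gsc$sets[.data$pathway]),
      overlap = purrr::map2_int(
        .data$hub, .data$pathway,
        function(a, b) length(intersect(nbs[[a]], gsc$sets[[b]]))
      ),
      pvalue = dplyr::if_else(
        .data$n_neighbours == 0, 1,
        hypergeom_upper_tail(.data$overlap, .data$n_pathway,
                             pmax(.data$n_neighbours, 1L), N)
      ),
      p_adjusted = p.adjust(.data$pvalue, method = "BH"),
      qsignificant = .data$p_adjusted <= fdr
    )
  class(out) <- c("enrichment_result", class(out))
  attr(out, "fdr") <- fdr
  attr(out, "background_size") <- N
  out
}

#' Pathways enriched for at least one hub
#'
#' @param res An `enrichment_result`.
#' @return Sorted character vector of pathway names significant (after FDR)
#'   for at least one hub.
#' @export
significant_pathways <- function(res) {
  stopifnot(is.data.frame(res), all(c("pathway", "qsignificant") %in% names(res)))
  sort(unique(res$pathway[res$qsignificant]))
}

#' Rewiring null for pathway-set overlap between hub lists
#'
#' Takes the pathways enriched for one hub list as the gold standard and
#' asks how many of them a degree-matched random hub list recovers on a
#' degree-preserving rewired network. Each replicate rewires the network,
#' samples a random list with the degree multiset of `hubs_other`, runs
#' neighbour enrichment, and counts the overlap of its significant pathways
#' with `reference_pathways`. The observed value is the overlap achieved by
#' the real `hubs_other` list on the real network.
#'
#' @param net PPI network.
#' @param reference_pathways Character vector: the gold-standard pathway set.
#' @param hubs_other The second hub list (see [po_score()]).
#' @param gsc A `geneset_collection`.
#' @param n_rep Number of replicates.
#' @param fdr Enrichment FDR (default 0.01).
#' @param seed Master integer seed.
#' @param n_swaps_per_edge Swap attempts per edge for the rewiring.
#' @return A `null_distribution` (scheme `"pathway_overlap"`) whose samples
#'   are overlap counts (non-negative integers bounded by
#'   `length(reference_pathways)`).
#' @export
pathway_overlap_null <- function(net, reference_pathways, hubs_other, gsc,
                                 n_rep = 1000, fdr = 0.01, seed = NULL,
                                 n_swaps_per_edge = 10) {
  net <- as_ppi_network(net, quiet = TRUE)
  reference_pathways <- unique(as.character(reference_pathways))
  h <- as_hub_ids(hubs_other)
  observed <- length(intersect(
    significant_pathways(enrich_neighbours(h, net, gsc, fdr = fdr)),
    reference_pathways
  ))
  if (length(reference_pathways) == 0) {
    return(new_null_distribution("pathway_overlap", rep(0, n_rep), 0))
  }
  deg <- igraph::degree(net)
  ref_deg <- list(unname(deg[h]), unname(deg[h]))
  seeds <- matrix(derive_seeds(seed, 2 * n_rep), ncol = 2)
  samples <- purrr::map_dbl(seq_len(n_rep), function(i) {
    rnet <- rewire_preserving_degrees(net, n_swaps_per_edge, seed = seeds[i, 1])
    rl <- sample_random_hub_lists(rnet,
      mode = "degree_matched", reference_degrees = ref_deg, seed = seeds[i, 2]
    )$list1
    length(intersect(
      significant_pathways(enrich_neighbours(rl, rnet, gsc, fdr = fdr)),
      reference_pathways
    ))
  })
  new_null_distribution("pathway_overlap", samples, observed)
}

#' Shared-neighbour overlap and special-gene over-representation
#'
#' Given two hub lists, computes (a) each list's pooled interaction
#' neighbours lying inside a chosen group of pathways, (b) the
#' hypergeometric significance of the two neighbour sets' intersection
#' against a background of `N` proteins, and (c) the hypergeometric
#' over-representation of that intersection in a special gene list (e.g.
#' curated cancer genes) against the collection's background universe.
#'
#' @param list1,list2 Hub lists (see [po_score()]).
#' @param net PPI network.
#' @param restrict_to Character vector of pathway names whose member genes
#'   delimit the neighbour sets; `NULL` uses all pathways in `gsc`.
#' @param gsc A `geneset_collection`.
#' @param special_genes Character vector of special genes (restricted to the
#'   collection background before testing).
#' @param N Background size for the neighbour-intersection test (default:
#'   collection background size).
#' @return Object of class `shared_neighbour_test`: list with `n`, `m`, `g`
#'   (neighbour-set sizes and intersection), `pvalue_overlap`, and
#'   `special_n`, `special_hits`, `pvalue_special`. Empty neighbour sets
#'   give `g = 0` and p-values of 1.
#' @export
shared_neighbour_geneset_test <- function(list1, list2, net, restrict_to = NULL,
                                          gsc, special_genes = character(0),
                                          N = NULL) {
  stopifnot(inherits(gsc, "geneset_collection"))
  net <- as_ppi_network(net, quiet = TRUE)
  N <- N %||% length(gsc$background)
  sel <- if (is.null(restrict_to)) names(gsc$sets) else {
    missing <- setdiff(restrict_to, names(gsc$sets))
    if (length(missing) > 0) {
      abort(sprintf("unknown pathway(s): %s", paste(missing, collapse = ", ")))
    }
    restrict_to
  }
  universe <- unique(unlist(gsc$sets[sel], use.names = FALSE))
  pooled_nb <- function(hl) {
    h <- as_hub_ids(hl)
    nb <- unique(unlist(.neighbour_sets(net, h), use.names = FALSE))
    intersect(setdiff(nb, h), universe)
  }
  nb1 <- pooled_nb(list1)
  nb2 <- pooled_nb(list2)
  g <- length(intersect(nb1, nb2))
  shared <- intersect(nb1, nb2)
  special <- intersect(unique(as.character(special_genes)), gsc$background)
  hits <- length(intersect(shared, special))
  structure(
    list(
      n = length(nb1), m = length(nb2), g = g, N = N,
      pvalue_overlap = if (length(nb1) == 0 || length(nb2) == 0) 1 else {
        hypergeom_upper_tail(g, length(nb1), length(nb2), N)
      },
      special_n = length(special), special_hits = hits,
      background_size = length(gsc$background),
      pvalue_special = if (g == 0 || length(special) == 0) 1 else {
        hypergeom_upper_tail(hits, length(special), g, length(gsc$background))
      }
    ),
    class = "shared_neighbour_test"
  )
}

#' @export
print.shared_neighbour_test <- function(x, ...) {
  cat(sprintf(
    "<shared_neighbour_test> %d and %d pathway-restricted neighbours share %d (N=%d): P = %.3g\n",
    x$n, x$m, x$g, x$N, x$pvalue_overlap
  ))
  cat(sprintf(
    "  special genes: %d of %d shared neighbours in a list of %d (background %d): P = %.3g\n",
    x$special_hits, x$g, x$special_n, x$background_size, x$pvalue_special
  ))
  invisible(x)
}
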