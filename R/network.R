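## Protein-protein interaction network handling. The network container is an
## undirected simple igraph object with gene symbols as vertex names; all
## user-facing builders also accept a two-column edge-list data frame.

#' Build a PPI network from an edge list
#'
#' Coerces a two-column edge-list data frame (gene symbols) or an existing
#' igraph object into an undirected simple graph: self-loops are dropped and
#' duplicate edges (in either orientation) are merged, with a message
#' reporting how many of each were removed.
#'
#' @param x Two-column data frame (interactor A, interactor B) or igraph.
#' @param quiet Suppress the cleanup message.
#' @return An undirected simple `igraph` with named vertices.
#' @examples
#' net <- as_ppi_network(data.frame(a = c("x", "y", "y"), b = c("y", "x", "z")))
#' igraph::ecount(net) # 2: x-y deduplicated
#' @export
as_ppi_network <- function(x, quiet = FALSE) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("edge list needs two columns")
    el <- data.frame(
      from = as.character(x[[1]]),
      to = as.character(x[[2]]),
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(el, directed = FALSE)
  } else {
    abort("`x` must be a two-column data frame or an igraph object")
  }
  n_loops <- sum(igraph::which_loop(g))
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- n_before - n_loops - igraph::ecount(g)
  if (!quiet && (n_loops > 0 || n_dup > 0)) {
    inform(sprintf(
      "PPI cleanup: dropped %d self-loop(s), merged %d duplicate edge(s)",
      n_loops, n_dup
    ))
  }
  g
}

#' Restrict a network to measured genes
#'
#' Keeps only nodes present in `measured_genes` and the edges with both
#' endpoints retained. This mirrors the usual preprocessing step of
#' intersecting an interactome with the genes quantified on an expression
#' platform before any hub analysis. Idempotent.
#'
#' @param net PPI network (igraph or edge-list data frame).
#' @param measured_genes Character vector of gene identifiers to keep.
#' @return Restricted `igraph`.
#' @export
restrict_to_measured <- function(net, measured_genes) {
  net <- as_ppi_network(net, quiet = TRUE)
  keep <- intersect(igraph::V(net)$name, as.character(measured_genes))
  if (length(keep) == 0) {
    abort("no network gene is among the measured genes; nothing to analyse")
  }
  igraph::induced_subgraph(net, keep)
}

#' Identify hub proteins
#'
#' Hubs are nodes with at least `min_degree` interaction partners (default 3,
#' the customary cut-off for interactome hub analyses).
#'
#' @param net PPI network.
#' @param min_degree Minimum number of interaction partners (>= 1).
#' @param source_label Optional free-text label recording where the list
#'   comes from (e.g. a dataset name); stored as an attribute.
#' @return A tibble with columns `hub` and `degree`, in lexicographic hub
#'   order, of class `hub_list`.
#' @export
get_hubs <- function(net, min_degree = 3, source_label = NULL) {
  stopifnot(min_degree >= 1)
  net <- as_ppi_network(net, quiet = TRUE)
  deg <- igraph::degree(net)
  keep <- names(deg)[deg >= min_degree]
  out <- tibble::tibble(hub = sort(keep), degree = as.integer(deg[sort(keep)]))
  class(out) <- c("hub_list", class(out))
  attr(out, "min_degree") <- min_degree
  attr(out, "source_label") <- source_label
  out
}

#' Interaction neighbours of a gene
#'
#' @param net PPI network.
#' @param gene Gene identifier; must be a network node.
#' @return Sorted character vector of adjacent genes (never includes `gene`).
#' @export
neighbours <- function(net, gene) {
  net <- as_ppi_network(net, quiet = TRUE)
  if (!gene %in% igraph::V(net)$name) {
    abort(sprintf("gene '%s' is not in the network", gene))
  }
  nb <- igraph::neighbors(net, gene)$name
  sort(setdiff(nb, gene))
}

.neighbour_sets <- function(net, genes) {
  adj <- igraph::adjacent_vertices(net, genes)
  stats::setNames(lapply(adj, function(v) v$name), genes)
}

#' Degree-preserving network randomization
#'
#' Randomizes interaction partners by repeated double-edge swaps: two edges
#' (a,b) and (c,d) are replaced by (a,d) and (c,b); proposals that would
#' create a self-loop or a duplicate edge are rejected. Every node keeps
#' exactly its original degree, so the rewired networks serve as the
#' topology-matched null for neighbourhood-overlap scores.
#'
#' @param net PPI network.
#' @param n_swaps_per_edge Swap attempts per edge (default 10, enough to
#'   decorrelate edge identities on sparse graphs).
#' @param seed Integer seed for reproducibility.
#' @return Rewired `igraph` with the identical degree sequence. Graphs with
#'   no legal swap (e.g. a triangle) come back unchanged.
#' @export
rewire_preserving_degrees <- function(net, n_swaps_per_edge = 10, seed = NULL) {
  net <- as_ppi_network(net, quiet = TRUE)
  m <- igraph::ecount(net)
  if (m < 2) return(net)
  if (!is.null(seed)) set.seed(as.integer(seed))
  niter <- max(1L, as.integer(ceiling(n_swaps_per_edge * m)))
  igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
}

#' Sample random protein lists from a network
#'
#' Draws a pair of node lists without replacement, either uniformly from the
#' node pool (`any_protein`) or constrained so each list's degree multiset
#' equals a reference multiset (`degree_matched`, ties among equal-degree
#' nodes broken uniformly at random). These are the building blocks of the
#' random-list and rewired-network null models.
#'
#' @param net PPI network.
#' @param length1,length2 Requested list lengths (ignored in `degree_matched`
#'   mode, where the reference multisets fix the lengths).
#' @param mode `"any_protein"` or `"degree_matched"`.
#' @param reference_degrees For `degree_matched`: list of two integer vectors,
#'   the degree multisets the two sampled lists must reproduce.
#' @param pool `"all"` to sample from every node (default) or `"hubs_only"`
#'   to restrict the `any_protein` pool to nodes of degree >= `min_degree`.
#' @param min_degree Hub cut-off used when `pool = "hubs_only"`.
#' @param seed Integer seed.
#' @return List with character vectors `list1` and `list2`.
#' @export
sample_random_hub_lists <- function(net, length1 = NULL, length2 = NULL,
                                    mode = c("any_protein", "degree_matched"),
                                    reference_degrees = NULL,
                                    pool = c("all", "hubs_only"),
                                    min_degree = 3, seed = NULL) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  net <- as_ppi_network(net, quiet = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  deg <- igraph::degree(net)
  nodes <- names(deg)

  if (mode == "any_protein") {
    if (is.null(length1) || is.null(length2)) {
      abort("any_protein mode needs `length1` and `length2`")
    }
    if (pool == "hubs_only") nodes <- nodes[deg[nodes] >= min_degree]
    if (length1 > length(nodes) || length2 > length(nodes)) {
      abort("requested list length exceeds the eligible node pool")
    }
    return(list(
      list1 = resample(nodes, length1),
      list2 = resample(nodes, length2)
    ))
  }

  if (is.null(reference_degrees) || length(reference_degrees) != 2) {
    abort("degree_matched mode needs `reference_degrees` = list of two degree vectors")
  }
  by_degree <- split(nodes, deg)
  draw_one <- function(ref) {
    tab <- table(ref)
    picked <- lapply(names(tab), function(d) {
      avail <- by_degree[[d]]
      if (is.null(avail) || length(avail) < tab[[d]]) {
        abort(sprintf(
          "cannot sample %d node(s) of degree %s: only %d available",
          tab[[d]], d, length(avail %||% character(0))
        ))
      }
      resample(avail, tab[[d]])
    })
    unlist(picked, use.names = FALSE)
  }
  list(
    list1 = draw_one(as.integer(reference_degrees[[1]])),
    list2 = draw_one(as.integer(reference_degrees[[2]]))
  )
}
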