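## End-to-end driver: restrict the interactome to genes measured in both
## cohorts, select signature hubs in each, score PO / POT / POT-e, run the
## requested null models and the pathway analyses, and emit a
## machine-readable report.

#' Default pipeline configuration
#'
#' All tunables in one list. Thresholds default to the conventional values
#' for this analysis: hub selection at permutation `alpha = 0.01` with 1000
#' permutations and hub degree cut-off 3, neighbourhood-overlap FDR 0.05,
#' pathway-enrichment FDR 0.01, direction-consistency level 0.05 with
#' Bernoulli `p = 0.5`, and 10 swap attempts per edge for rewiring.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    alpha = 0.01,
    min_degree = 3,
    n_perm = 1000,
    overlap_fdr = 0.05,
    enrich_fdr = 0.01,
    alpha_dir = 0.05,
    p_dir = 0.5,
    background_n = NULL, # NULL: genes with both PPI and expression data
    nulls = character(0), # subset of c("lists", "rewire", "phenotype")
    n_rep = 100,
    n_perm_null = 100, # inner hub-selection permutations in the phenotype null
    n_swaps_per_edge = 10,
    random_list_pool = "all",
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

.report_score <- function(rep) {
  if (is.null(rep)) return(NULL)
  rep[c("k", "L1", "L2", "T12", "T21", "PO12", "PO21", "PO",
        "POT12", "POT21", "POT", "variant")]
}

.report_null <- function(nd) {
  if (is.null(nd)) return(NULL)
  list(
    scheme = nd$scheme, n_rep = length(nd$samples), mean = nd$mean,
    observed = nd$observed, empirical_p = nd$empirical_p,
    samples = nd$samples
  )
}

#' Run the full reproducibility pipeline on two cohorts
#'
#' Stages, in order: restrict the network to genes measured in both
#' datasets; select signature hubs per dataset; compute PO, POT and POT-e
#' between the two lists; run the configured null models; if a gene-set
#' collection is given, run neighbour enrichment per list and the pathway
#' overlap. Every randomized stage consumes a named sub-seed derived from
#' `config$seed`, so a rerun with the same inputs is byte-identical.
#'
#' @param ds1,ds2 `expression_dataset`s, or character paths given as
#'   `c(expr, labels)` TSV pairs.
#' @param net PPI network (igraph, edge-list data frame, or a file path).
#' @param gsc Optional `geneset_collection` (or GMT file path).
#' @param config List from [default_config()].
#' @param out Optional path: the report is also written as JSON.
#' @return The report: a nested list of class `hubrep_report` with elements
#'   `params`, `n_background`, `hubs1`, `hubs2`, `scores`, `nulls`,
#'   `pathways`. If either hub list is empty the scores carry a
#'   `"no hubs selected"` note instead of values.
#' @export
run_full_pipeline <- function(ds1, ds2, net, gsc = NULL,
                              config = default_config(), out = NULL) {
  if (is.character(ds1)) ds1 <- read_expression(ds1[1], ds1[2])
  if (is.character(ds2)) ds2 <- read_expression(ds2[1], ds2[2])
  if (is.character(net)) net <- read_ppi(net)
  if (is.character(gsc)) gsc <- read_gmt(gsc)
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 6)

  inform("stage 1/5: restricting network to genes measured in both cohorts")
  both <- intersect(measured_genes(ds1), measured_genes(ds2))
  rnet <- restrict_to_measured(net, both)
  N <- cfg$background_n %||% igraph::vcount(rnet)

  inform("stage 2/5: selecting signature hubs in each cohort")
  h1 <- select_signature_hubs(ds1, rnet, alpha = cfg$alpha,
    min_degree = cfg$min_degree, n_perm = cfg$n_perm, seed = seeds[1])
  h2 <- select_signature_hubs(ds2, rnet, alpha = cfg$alpha,
    min_degree = cfg$min_degree, n_perm = cfg$n_perm, seed = seeds[2])
  l1 <- as_hub_ids(h1)
  l2 <- as_hub_ids(h2)

  scores <- if (length(l1) == 0 || length(l2) == 0) {
    list(note = "no hubs selected in at least one cohort")
  } else {
    inform("stage 3/5: scoring PO / POT / POT-e")
    list(
      po = .report_score(po_score(l1, l2)),
      pot = .report_score(pot_score(l1, l2, rnet, N = N, fdr = cfg$overlap_fdr)),
      pot_e = .report_score(pot_e_score(l1, l2, rnet, N = N, ds1 = ds1,
        ds2 = ds2, fdr = cfg$overlap_fdr, alpha_dir = cfg$alpha_dir,
        p_dir = cfg$p_dir))
    )
  }

  nulls <- list()
  if (length(cfg$nulls) > 0 && length(l1) > 0 && length(l2) > 0) {
    inform(sprintf("stage 4/5: null models (%s)", paste(cfg$nulls, collapse = ", ")))
    obs <- scores$pot$POT
    if ("lists" %in% cfg$nulls) {
      nulls$random_lists <- .report_null(null_random_lists(
        rnet, length(l1), length(l2), N = N, n_rep = cfg$n_rep,
        seed = seeds[3], fdr = cfg$overlap_fdr, pool = cfg$random_list_pool,
        min_degree = cfg$min_degree, observed = obs
      ))
    }
    if ("rewire" %in% cfg$nulls) {
      nulls$rewired_network <- .report_null(null_rewired(
        rnet, l1, l2, N = N, n_rep = cfg$n_rep, seed = seeds[4],
        fdr = cfg$overlap_fdr, n_swaps_per_edge = cfg$n_swaps_per_edge,
        observed = obs
      ))
    }
    if ("phenotype" %in% cfg$nulls) {
      nulls$phenotype_permutation <- .report_null(null_phenotype_permutation(
        ds1, ds2, rnet, n_rep = cfg$n_rep, seed = seeds[5], score = "POT",
        N = N, alpha = cfg$alpha, min_degree = cfg$min_degree,
        n_perm = cfg$n_perm_null, fdr = cfg$overlap_fdr
      ))
    }
  }

  pathways <- NULL
  if (!is.null(gsc) && length(l1) > 0 && length(l2) > 0) {
    inform("stage 5/5: pathway enrichment and overlap")
    e1 <- enrich_neighbours(l1, rnet, gsc, fdr = cfg$enrich_fdr)
    e2 <- enrich_neighbours(l2, rnet, gsc, fdr = cfg$enrich_fdr)
    s1 <- significant_pathways(e1)
    s2 <- significant_pathways(e2)
    pathways <- list(
      significant1 = s1, significant2 = s2,
      shared = intersect(s1, s2),
      n_shared = length(intersect(s1, s2))
    )
  }

  report <- structure(list(
    params = cfg[setdiff(names(cfg), "background_n")],
    n_background = N,
    hubs1 = as.data.frame(h1),
    hubs2 = as.data.frame(h2),
    n_selected1 = length(l1),
    n_selected2 = length(l2),
    scores = scores,
    nulls = nulls,
    pathways = pathways
  ), class = "hubrep_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Write a pipeline report as JSON
#'
#' Full precision; reruns with identical inputs and seeds produce
#' byte-identical files.
#'
#' @param report A `hubrep_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @export
print.hubrep_report <- function(x, ...) {
  cat(sprintf(
    "<hubrep_report> background N = %d; %d and %d signature hubs\n",
    x$n_background, x$n_selected1, x$n_selected2
  ))
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  if (!is.null(x$scores$po)) {
    cat(sprintf(
      "  PO = %s, POT = %s, POT-e = %s\n",
      pct(x$scores$po$PO), pct(x$scores$pot$POT), pct(x$scores$pot_e$POT)
    ))
  } else {
    cat(sprintf("  scores: %s\n", x$scores$note))
  }
  for (nm in names(x$nulls)) {
    nd <- x$nulls[[nm]]
    cat(sprintf(
      "  null %s: mean = %s, empirical p = %.4g\n",
      nm, pct(nd$mean), nd$empirical_p
    ))
  }
  if (!is.null(x$pathways)) {
    cat(sprintf(
      "  pathways: %d and %d significant, %d shared\n",
      length(x$pathways$significant1), length(x$pathways$significant2),
      x$pathways$n_shared
    ))
  }
  invisible(x)
}
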