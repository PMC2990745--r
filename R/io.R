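## Readers and writers for the plain-text formats the pipeline consumes:
## TSV edge lists / SIF for the interactome, TSV matrices plus label files
## for expression, GMT for gene sets, TSV for hub lists.

#' Read a PPI network from a TSV edge list or SIF file
#'
#' Two-column headerless TSV (interactor A, interactor B) or SIF
#' (`A relation B`, whitespace- or tab-delimited; the middle column is
#' ignored). Duplicate unordered pairs are merged and self-loops dropped,
#' with a message reporting the counts.
#'
#' @param path File path.
#' @param format `"auto"` (3+ columns means SIF), `"tsv"` or `"sif"`.
#' @param quiet Suppress the cleanup message.
#' @return An `igraph` PPI network.
#' @export
read_ppi <- function(path, format = c("auto", "tsv", "sif"), quiet = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty PPI file")
  parts <- strsplit(lines, "[ \t]+")
  ncols <- lengths(parts)
  bad <- which(ncols < 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed PPI line %d: '%s'", bad[1], lines[bad[1]]))
  }
  if (format == "auto") format <- if (all(ncols >= 3)) "sif" else "tsv"
  if (format == "sif") {
    bad <- which(ncols < 3)
    if (length(bad) > 0) {
      abort(sprintf("malformed SIF line %d: '%s'", bad[1], lines[bad[1]]))
    }
    ## SIF allows several targets per line: A rel B C ...
    el <- do.call(rbind, lapply(parts, function(p) {
      cbind(p[1], p[seq(3, length(p))])
    }))
  } else {
    el <- do.call(rbind, lapply(parts, function(p) p[1:2]))
  }
  as_ppi_network(as.data.frame(el, stringsAsFactors = FALSE), quiet = quiet)
}

#' Write a PPI network as a two-column TSV edge list
#' @param net PPI network.
#' @param path Output path.
#' @export
write_ppi <- function(net, path) {
  net <- as_ppi_network(net, quiet = TRUE)
  el <- igraph::as_edgelist(net)
  readr::write_tsv(
    tibble::tibble(from = el[, 1], to = el[, 2]),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read phenotype labels
#'
#' Two-column TSV (sample id, class), with or without a header line.
#'
#' @param path File path.
#' @return Tibble with columns `sample` and `class`.
#' @export
read_labels <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- identical(tolower(first[1:2]), c("sample", "class"))
  df <- readr::read_tsv(path,
    col_names = if (has_header) TRUE else c("sample", "class"),
    skip = 0, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(df)[1:2] <- c("sample", "class")
  if (anyDuplicated(df$sample)) abort("duplicate sample ids in label file")
  df[, 1:2]
}

#' Read an expression dataset
#'
#' Expression TSV: first column gene id, header row of sample ids. Duplicate
#' rows for one gene are collapsed by keeping the row of maximal variance
#' (with a message). Labels come from a companion two-column TSV
#' (sample id, class); samples are matched by id and must cover all columns.
#'
#' @param path Expression matrix TSV.
#' @param labels_path Label TSV (see [read_labels()]).
#' @param ... Passed to [expression_dataset()] (e.g. `positive_class`).
#' @return An `expression_dataset`.
#' @export
read_expression <- function(path, labels_path, ...) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1])
  if (!is.numeric(mat)) abort("expression values must be numeric")
  if (anyDuplicated(colnames(mat))) abort("duplicate sample ids in expression file")
  if (anyDuplicated(genes)) {
    v <- apply(mat, 1, var)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(ix) {
      ix[which.max(v[ix])]
    }), use.names = FALSE)
    inform(sprintf(
      "collapsed %d duplicate gene row(s) by maximal variance",
      length(genes) - length(keep)
    ))
    keep <- sort(keep) # preserve original row order
    mat <- mat[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(mat) <- genes
  lab <- read_labels(labels_path)
  missing <- setdiff(colnames(mat), lab$sample)
  if (length(missing) > 0) {
    abort(sprintf("no label for sample(s): %s", paste(missing, collapse = ", ")))
  }
  labels <- lab$class[match(colnames(mat), lab$sample)]
  expression_dataset(mat, labels, ...)
}

#' Write an expression dataset (matrix TSV + label TSV)
#' @param ds An `expression_dataset`.
#' @param path Expression matrix output path.
#' @param labels_path Label output path.
#' @export
write_expression <- function(ds, path, labels_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- tibble::as_tibble(ds$values, rownames = "gene")
  readr::write_tsv(df, path)
  readr::write_tsv(
    tibble::tibble(sample = colnames(ds$values), class = ds$labels),
    labels_path
  )
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-delimited.
#'
#' @param path File path.
#' @param background Optional background universe; defaults to the union of
#'   all members.
#' @return A `geneset_collection`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d (need name, description, >=1 gene)", bad[1]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT")
  geneset_collection(sets, background = background)
}

#' Write a gene-set collection as GMT
#' @param gsc A `geneset_collection`.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(gsc, path, description = "na") {
  stopifnot(inherits(gsc, "geneset_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, description, gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a hub list from TSV
#'
#' Accepts the TSV written by [write_hublist()] (columns `hub`, optionally
#' `degree`) or a single-column headerless file. When the file carries a
#' `selected` column (a serialized signature-hub table), only the selected
#' rows are returned.
#'
#' @param path File path.
#' @return Character vector of hub identifiers.
#' @export
read_hublist <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if ("hub" %in% tolower(first)) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    names(df) <- tolower(names(df))
    if ("selected" %in% names(df)) df <- df[which(df$selected), ]
    hubs <- as.character(df$hub)
  } else {
    hubs <- as.character(readr::read_tsv(path, col_names = "hub",
      show_col_types = FALSE, col_types = "c")$hub)
  }
  if (anyDuplicated(hubs)) abort("duplicate hubs in hub list file")
  hubs
}

#' Write a hub list (or signature-hub table) as TSV
#' @param hubs Hub list, `signature_hub_table` or character vector.
#' @param path Output path.
#' @export
write_hublist <- function(hubs, path) {
  if (is.data.frame(hubs)) {
    readr::write_tsv(tibble::as_tibble(as.data.frame(hubs)), path)
  } else {
    readr::write_tsv(tibble::tibble(hub = as.character(hubs)), path)
  }
  invisible(path)
}

#' Write a synthetic scenario to disk as pipeline input files
#'
#' Materializes network, expression, labels and pathway files for a
#' scenario, in the formats the readers above consume.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_scenario_files <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_network(scenario)
  ds <- make_expression(scenario, net)
  gsc <- make_genesets(scenario, net)
  paths <- list(
    ppi = file.path(dir, "net.tsv"),
    expr1 = file.path(dir, "expr1.tsv"), labels1 = file.path(dir, "labels1.tsv"),
    expr2 = file.path(dir, "expr2.tsv"), labels2 = file.path(dir, "labels2.tsv"),
    gmt = file.path(dir, "pathways.gmt")
  )
  write_ppi(net, paths$ppi)
  write_expression(ds$ds1, paths$expr1, paths$labels1)
  write_expression(ds$ds2, paths$expr2, paths$labels2)
  write_gmt(gsc, paths$gmt)
  invisible(paths)
}
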