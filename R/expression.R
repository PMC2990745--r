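## Two-group expression container. Correlation-based statistics degenerate
## below 3 samples per group, so the constructor rejects smaller groups.

#' Construct a two-group expression dataset
#'
#' Bundles a genes-by-samples numeric matrix with a binary phenotype label
#' per sample. The class whose within-group correlations are reported first
#' (and whose sign anchors correlation-change directions) is the
#' `positive_class`; for cohort data this is conventionally the metastatic
#' group.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns; no missing values.
#' @param labels Character/factor vector, one label per column of `values`,
#'   with exactly two distinct values and at least 3 samples in each.
#' @param positive_class Which label is the positive (case) group. Defaults
#'   to `"metastatic"` when present, otherwise the first label
#'   alphabetically.
#' @param name Optional free-text dataset name.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, labels, positive_class = NULL,
                               name = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values))) abort("`values` needs gene rownames")
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids in `values`")
  if (anyNA(values)) abort("`values` contains missing values")
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    abort("one label per sample (column) is required")
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("exactly two phenotype classes are required")
  if (any(table(labels) < 3)) {
    abort("each phenotype class needs >= 3 samples (correlation is degenerate below that)")
  }
  if (is.null(positive_class)) {
    positive_class <- if ("metastatic" %in% classes) "metastatic" else classes[1]
  }
  if (!positive_class %in% classes) {
    abort(sprintf("positive_class '%s' is not among the labels", positive_class))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids")
  structure(
    list(
      values = values,
      labels = labels,
      positive_class = positive_class,
      negative_class = setdiff(classes, positive_class),
      name = name
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<expression_dataset%s> %d genes x %d samples (%s)\n",
    if (is.null(x$name)) "" else paste0(": ", x$name),
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Genes measured in a dataset
#' @param ds An `expression_dataset`.
#' @return Character vector of gene identifiers.
#' @export
measured_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  rownames(ds$values)
}

## logical mask of the positive-class samples
.positive_mask <- function(ds) ds$labels == ds$positive_class

#' Permute the phenotype labels of a dataset
#'
#' Randomly reassigns the existing labels to samples (group sizes preserved),
#' leaving the expression values, and hence the global correlation structure,
#' untouched. This is the elementary move of the phenotype-permutation null.
#'
#' @param ds An `expression_dataset`.
#' @param seed Integer seed.
#' @return A new `expression_dataset` with shuffled labels.
#' @export
permute_labels <- function(ds, seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  expression_dataset(ds$values, sample(ds$labels),
    positive_class = ds$positive_class, name = ds$name
  )
}
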