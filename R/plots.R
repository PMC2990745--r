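## ggplot2 visualizations for the main result types.

#' Volcano-style plot: co-expression-change
#'   statistic against -log10 permutation p, selected hubs highlighted.
#' @param object A `signature_hub_table`.
#' @export
autoplot.signature_hub_table <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!is.na(.data$pvalue))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$stat, y = -log10(.data$pvalue), colour = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "|difference of group-average PCC|",
      y = expression(-log[10] ~ "permutation p"),
      colour = sprintf("p < %.3g", attr(object, "alpha")),
      title = "Signature hub selection"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of the null samples with the
#'   observed score marked.
#' @param object A `null_distribution`.
#' @export
autoplot.null_distribution <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = "null score", y = "replicates",
      title = sprintf("Null model: %s", object$scheme),
      subtitle = if (is.na(object$observed)) NULL else {
        sprintf("observed = %.3g, empirical p = %.3g",
                object$observed, object$empirical_p)
      }
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$observed)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$observed, colour = "firebrick", linewidth = 1
    )
  }
  p
}

#' Bar chart of the directional and averaged scores.
#' @param object A `score_report`.
#' @export
autoplot.score_report <- function(object, ...) {
  lab <- if (object$variant == "coexpression_restricted") "POT-e" else "POT"
  df <- tibble::tibble(
    score = factor(
      c("PO 1->2", "PO 2->1", "PO", paste(lab, c("1->2", "2->1")), lab),
      levels = c("PO 1->2", "PO 2->1", "PO", paste(lab, c("1->2", "2->1")), lab)
    ),
    value = c(object$PO12, object$PO21, object$PO,
              object$POT12, object$POT21, object$POT),
    family = rep(c("protein overlap", "topology overlap"), each = 3)
  ) |> dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$value,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL,
                  title = "Hub-list reproducibility") +
    ggplot2::theme_minimal()
}

#' Dot plot of the significant (hub, pathway)
#'   enrichments.
#' @param object An `enrichment_result`.
#' @param max_rows Show at most this many most-significant rows.
#' @export
autoplot.enrichment_result <- function(object, max_rows = 30, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$qsignificant) |>
    dplyr::arrange(.data$p_adjusted) |>
    head(max_rows)
  if (nrow(df) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no significant enrichment") +
        ggplot2::theme_void()
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$hub, y = .data$pathway,
    size = .data$overlap, colour = -log10(.data$p_adjusted)
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "signature hub", y = NULL, size = "neighbours\nin pathway",
      colour = expression(-log[10] ~ "adj. p"),
      title = "Neighbour enrichment in pathways"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
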