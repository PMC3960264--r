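# ggplot2 views of the main result types.

#' Plot a read-category tally
#'
#' Bar chart of category fractions, faceted into the annotated
#' (rRNA/tRNA/mRNA) and non-annotated (intergenic/antisense/misc_rna)
#' panels used in survey-style reporting.
#'
#' @param object An `srna_category_tally`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srna_category_tally <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$category, y = .data$panel_fraction,
    fill = .data$category
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = NULL, y = "fraction of panel reads",
      title = "Read categories"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a candidate call
#'
#' Stacked bars of candidate counts per class, split by replicon kind.
#'
#' @param object An `srna_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srna_call <- function(object, ...) {
  df <- dplyr::count(object$candidates, .data$srna_class, .data$replicon_kind)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$srna_class, y = .data$n, fill = .data$replicon_kind
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "candidates", fill = NULL,
      title = "Candidate sRNAs by class and replicon kind"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-base coverage profile of one cluster
#'
#' @param cluster One-row cluster tibble.
#' @param reads The read tibble the cluster was built from.
#' @return A ggplot object (depth along the cluster span, 1-based axis).
#' @export
plot_cluster_coverage <- function(cluster, reads) {
  depth <- cluster_coverage(cluster, reads)
  df <- tibble(position = cluster$start + seq_along(depth), depth = depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = paste0(cluster$replicon, " (", cluster$strand, ")"),
      y = "read depth",
      title = cluster$cluster_id
    ) +
    ggplot2::theme_minimal()
}
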