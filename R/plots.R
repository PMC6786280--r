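## ggplot2 visualisations for the main result types.

#' Plot a gene-aligned profile
#'
#' @param object a `meth_profile` (from [gene_aligned_profile()],
#'   [event_frequency_profile()] or [site_class_profile()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot meth_profile
#' @export
autoplot.meth_profile <- function(object, ...) {
  df <- as_tibble(object)
  colour_col <- intersect(c("event_type", "site_class"), names(df))
  p <- if (length(colour_col)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value,
                                     colour = .data[[colour_col[1]]]))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value))
  }
  p + ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("distance from %s end (bp)", attr(object, "end")),
      y = attr(object, "kind")
    ) +
    ggplot2::theme_minimal()
}

#' Density plot of percent-methylation-change
#'
#' Kernel density of the eligible signed percent-methylation-change
#' values of a comparison, with the partial/full cutoff marked.
#'
#' @param changes tibble with a `pmc` column (from
#'   [change_density_inputs()]).
#' @param full_cutoff |pmc| marking full changes (default 90).
#' @return a ggplot.
#' @export
plot_change_density <- function(changes, full_cutoff = 90) {
  ggplot2::ggplot(changes, ggplot2::aes(x = .data$pmc)) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(-full_cutoff, full_cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = "percent-methylation-change", y = "density") +
    ggplot2::theme_minimal()
}

#' PCA plot of sample structure
#'
#' @param object a `sample_structure` from [sample_structure()].
#' @param ... unused.
#' @return a ggplot of the first two principal components.
#' @method autoplot sample_structure
#' @export
autoplot.sample_structure <- function(object, ...) {
  ve <- attr(object$pca, "variance_explained")
  ggplot2::ggplot(object$pca,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$column)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Bar plot of exon state-bin proportions
#'
#' @param proportions output of [state_proportions()].
#' @return a ggplot.
#' @export
plot_state_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$tissue, y = .data$proportion,
                               fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of exons") +
    ggplot2::theme_minimal()
}

#' Information-content plot of a position frequency matrix
#'
#' @param object a `pfm` from [motif_matrix()].
#' @param ... unused.
#' @return a ggplot of per-position information content.
#' @method autoplot pfm
#' @export
autoplot.pfm <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$bits)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "offset from methylated C (bp)",
                  y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
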