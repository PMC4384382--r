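#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mixture fit over the expression density
#'
#' Kernel density of the fitted log2 expression values with the two
#' weighted Gaussian components and, optionally, the FDR class boundaries.
#'
#' @param object A `"mixture_fit"`.
#' @param boundaries Optional [class_boundaries()] row to draw as dashed
#'   vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture_fit <- function(object, boundaries = NULL, ...) {
  grid <- seq(min(object$data), max(object$data), length.out = 512)
  comp <- dplyr::bind_rows(
    tibble::tibble(x = grid, component = "LE",
                   density = (1 - object$weight_he) *
                     dnorm(grid, object$mu_le, object$sd_le)),
    tibble::tibble(x = grid, component = "HE",
                   density = object$weight_he *
                     dnorm(grid, object$mu_he, object$sd_he))
  )
  p <- ggplot2::ggplot(tibble::tibble(x = object$data), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_density(colour = "grey30") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "log2 normalized expression", y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    b <- c(boundaries$b_low, boundaries$b_high)
    b <- b[is.finite(b)]
    if (length(b) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = b, linetype = "dashed")
    }
  }
  p
}

#' Plot PCA sample scores
#'
#' @param object An `"atlas_pca"`.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2, coloured by subtype when available.
#' @export
autoplot.atlas_pca <- function(object, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if ("subtype" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$subtype), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of significant DE gene counts per pair
#'
#' @param de_counts Output of [count_de()].
#' @return A ggplot tile map, faceted by fold-change cutoff.
#' @export
plot_de_counts <- function(de_counts) {
  ggplot2::ggplot(de_counts,
                  ggplot2::aes(x = .data$subtype_a, y = .data$subtype_b,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white",
                       size = 3) +
    ggplot2::facet_wrap(~cutoff, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL, fill = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked bars of group-summed PSI
#'
#' @param grouped Output of [group_psi()] at subtype level.
#' @param gene Gene to display.
#' @return A ggplot stacked bar chart of PSI by isoform group per subtype.
#' @export
plot_group_psi <- function(grouped, gene) {
  df <- grouped[grouped$gene_id == gene, ]
  if (nrow(df) == 0) stop_atlas(sprintf("gene '%s' not in table", gene), "data")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$psi,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = gene, x = NULL, y = "PSI") +
    ggplot2::theme_minimal()
}
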