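#' Plot the category partition of a classification
#'
#' Bar chart of gene counts per specificity category, annotated with the
#' percentage of the gene total.
#'
#' @param object A `gene_classification` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_classification
#' @export
autoplot.gene_classification <- function(object, ...) {
  counts <- category_percentages(category_counts(object))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0(.data$percent, "%")),
      vjust = -0.3, size = 3
    ) +
    ggplot2::labs(
      x = NULL, y = "genes",
      title = paste0(
        "Specificity categories",
        if (!is.null(attr(object, "target"))) {
          paste0(" (target: ", attr(object, "target"), ")")
        }
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Pie chart of transcript-pool fractions
#'
#' @param pf Pool-fraction tibble from [pool_fractions()].
#' @return A ggplot object.
#' @export
plot_pool_fractions <- function(pf) {
  pf <- pf[pf$fraction > 0, , drop = FALSE]
  ggplot2::ggplot(
    pf,
    ggplot2::aes(x = "", y = .data$fraction, fill = .data$category)
  ) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "category",
      title = "Transcript pool by category"
    ) +
    ggplot2::theme_void()
}

#' Plot a tissue-sharing network
#'
#' Draws the bipartite network of enriched tissue combinations (node area
#' proportional to gene count, i.e. radius to its square root) and their
#' member tissues, with a force-directed layout.
#'
#' @param object A `tissue_sharing_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tissue_sharing_network
#' @export
autoplot.tissue_sharing_network <- function(object, ...) {
  if (nrow(object$groups) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no group-enriched genes") +
        ggplot2::theme_void()
    )
  }
  g <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(
    name = igraph::V(g)$name,
    kind = igraph::V(g)$kind,
    size = igraph::V(g)$size,
    x = xy[, 1], y = xy[, 2]
  )
  ed <- tibble(
    x = nodes$x[match(object$edges$combo_id, nodes$name)],
    y = nodes$y[match(object$edges$combo_id, nodes$name)],
    xend = nodes$x[match(object$edges$tissue, nodes$name)],
    yend = nodes$y[match(object$edges$tissue, nodes$name)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y, colour = .data$kind, size = .data$size
      )
    ) +
    ggplot2::geom_text(
      data = nodes[nodes$kind == "tissue", , drop = FALSE],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(tissue = "grey40", group = "darkorange")
    ) +
    ggplot2::labs(title = "Tissue-sharing network of group-enriched genes") +
    ggplot2::theme_void()
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param cc Correlation matrix from [spearman_matrix()].
#' @return A ggplot object.
#' @export
plot_spearman <- function(cc) {
  df <- tibble(
    a = rep(rownames(cc), times = ncol(cc)),
    b = rep(colnames(cc), each = nrow(cc)),
    rho = as.vector(cc)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 0.5,
      limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
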