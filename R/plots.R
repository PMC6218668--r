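#' Centrality-vs-centrality scatterplot
#'
#' The discrimination plots of the hub workflow: one point per node, e.g.
#' topological coefficient against radiality.  Points from
#' [rank_nodes()]-selected nodes can be highlighted by passing their ids.
#'
#' @param records a tibble from [centrality_table()].
#' @param x,y measure names (see [rank_nodes()]).
#' @param highlight optional character vector of node ids drawn in colour
#'   and labelled.
#' @return A ggplot object.
#' @export
plot_centrality_scatter <- function(records, x = "tn", y = "radiality",
                                    highlight = NULL) {
  pts <- scatter_points(records, x, y)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = attr(pts, "x_measure"), y = attr(pts, "y_measure")) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    sel <- filter(pts, .data$node_id %in% !!highlight)
    p <- p +
      ggplot2::geom_point(data = sel, colour = "red", size = 2) +
      ggplot2::geom_text(data = sel,
                         ggplot2::aes(label = .data$node_id),
                         vjust = -0.8, size = 3, colour = "red")
  }
  p
}

#' Degree-class distribution plots
#'
#' Plots the average clustering coefficient (or neighborhood
#' connectivity) per degree class on log-log axes.
#'
#' @param dist a tibble from [clustering_connectivity_distributions()]
#'   (either element).
#' @return A ggplot object.
#' @export
plot_degree_class_distribution <- function(dist) {
  value_col <- setdiff(names(dist), "degree")[1]
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$degree,
                                     y = .data[[value_col]])) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "degree", y = value_col) +
    ggplot2::theme_minimal()
}
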