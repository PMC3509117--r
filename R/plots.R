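#' Plot methods
#'
#' ggplot2 visualisations of the package's result objects: a heatmap for
#' distance matrices, a scatter configuration for MDS embeddings, and a
#' force-directed layout for haplotype networks (node area proportional to
#' sample multiplicity, median vectors as small open points).
#'
#' @param object A `ystr_dist`, `ystr_mds` or `ystr_network` object.
#' @param ... Ignored.
#' @param seed Layout seed for the network plot.
#' @return A ggplot object.
#' @name ystrhap-plots
NULL

#' @rdname ystrhap-plots
#' @export
autoplot.ystr_dist <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$to, .data$from, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$measure) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname ystrhap-plots
#' @export
autoplot.ystr_mds <- function(object, ...) {
  stopifnot(sum(startsWith(names(object), "dim")) >= 2)
  ggplot2::ggplot(object, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
      vjust = -0.8, size = 3
    ) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2") +
    ggplot2::theme_minimal()
}

#' @rdname ystrhap-plots
#' @export
autoplot.ystr_network <- function(object, ..., seed = 1L) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- network_nodes(object) |>
    dplyr::mutate(x = xy[, 1], y = xy[, 2])
  edges <- network_edges(object) |>
    dplyr::left_join(
      dplyr::select(nodes, "node", x0 = "x", y0 = "y"),
      by = c("from" = "node")
    ) |>
    dplyr::left_join(
      dplyr::select(nodes, "node", x1 = "x", y1 = "y"),
      by = c("to" = "node")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, !.data$median_vector),
      ggplot2::aes(.data$x, .data$y, size = .data$n),
      colour = "steelblue"
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, .data$median_vector),
      ggplot2::aes(.data$x, .data$y),
      shape = 21, fill = "white", size = 1.5
    ) +
    ggplot2::scale_size_area(max_size = 8, name = "n") +
    ggplot2::theme_void()
}

#' @rdname ystrhap-plots
#' @param data A haplotype data frame (for `plot_diversity()`).
#' @export
plot_diversity <- function(data, ...) {
  diversity_summary(data, ...) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$population, .data$hd), y = .data$hd
    )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$hd - .data$hd_sd, 0),
      ymax = pmin(.data$hd + .data$hd_sd, 1)
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Haplotype diversity") +
    ggplot2::theme_minimal()
}
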