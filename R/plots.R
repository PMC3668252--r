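# ggplot2 views of the main result types.

#' Plot a median-joining haplotype network
#'
#' Observed haplotypes are drawn as circles sized by their sampled count and
#' coloured by species; median (hypothetical, unsampled) vectors as small
#' black points.  Edge labels give mutational steps where > 1.
#'
#' @param object An `mj_network`.
#' @param layout_seed Seed for the force-directed layout (layout only; the
#'   topology is deterministic).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mj_network <- function(object, layout_seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$name)]
  edges$y <- nodes$y[match(edges$from, nodes$name)]
  edges$xend <- nodes$x[match(edges$to, nodes$name)]
  edges$yend <- nodes$y[match(edges$to, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey40") +
    ggplot2::geom_text(data = edges[edges$weight > 1, ],
                       ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                    y = (.data$y + .data$yend) / 2,
                                    label = .data$weight),
                       size = 3, vjust = -0.4) +
    ggplot2::geom_point(data = nodes[nodes$is_median, ],
                        ggplot2::aes(.data$x, .data$y), size = 1.5,
                        colour = "black") +
    ggplot2::geom_point(data = nodes[!nodes$is_median, ],
                        ggplot2::aes(.data$x, .data$y,
                                     size = .data$count,
                                     colour = .data$species)) +
    ggplot2::geom_text(data = nodes[!nodes$is_median, ],
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Haplotype network: %s", object$locus))
}

#' Plot per-population haplotype frequencies of a panel
#'
#' @param object A `haplotype_panel`.
#' @param ... Unused.
#' @return A ggplot object (stacked bars per population).
#' @export
autoplot.haplotype_panel <- function(object, ...) {
  ggplot2::ggplot(haplotype_frequencies(object),
                  ggplot2::aes(x = .data$population, y = .data$count,
                               fill = .data$name)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(y = "haplotype frequency", fill = "haplotype",
                  title = sprintf("Haplotype distribution: %s", object$locus)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot germination rates with Wilson intervals
#'
#' @param summary Output of [germination_summary()].
#' @return A ggplot object.
#' @export
plot_germination <- function(summary) {
  ggplot2::ggplot(summary$rates,
                  ggplot2::aes(x = .data$taxon, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high), width = 0.2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(y = "spore germination rate", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot generation-class posteriors per individual
#'
#' @param classification The classification tibble of a `hybrid_report`.
#' @return A ggplot object (stacked posterior bars per individual).
#' @export
plot_class_posteriors <- function(classification) {
  long <- tidyr::pivot_longer(classification, dplyr::starts_with("post_"),
                              names_to = "class", values_to = "posterior",
                              names_prefix = "post_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$posterior,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "posterior") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
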