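# ggplot2 views of explored networks and their statistics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reaction network
#'
#' Node-and-edge view with nodes colored by the minimax bottleneck barrier
#' from the seed (the barrier of the rate-limiting step on the most
#' favorable route to each species) and edges colored by their forward
#' barrier. Layout is a deterministic circle to keep repeated renders
#' identical.
#'
#' @param object a `reaction_network`.
#' @param source_key node used as the origin for bottleneck coloring
#'   (default: the first seed).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.reaction_network <- function(object,
                                      source_key = object$nodes$key[object$nodes$seed][1],
                                      ...) {
  nodes <- object$nodes
  edges <- object$edges
  n <- nrow(nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  pos <- tibble::tibble(key = nodes$key, x = cos(theta), y = sin(theta))
  fav <- kinetically_favorable_products(object, source_key)
  pos$bottleneck <- fav$bottleneck[match(pos$key, fav$key)]
  seg <- dplyr::left_join(edges, pos, by = c(from = "key"))
  seg <- dplyr::left_join(seg, pos, by = c(to = "key"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, color = .data$delta_g_forward),
      linewidth = 0.6) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$bottleneck),
      shape = 21, size = 4, color = "grey20") +
    ggplot2::scale_color_viridis_c(name = "edge ΔG‡ (kcal/mol)") +
    ggplot2::scale_fill_viridis_c(name = "bottleneck ΔG‡ (kcal/mol)",
                                  option = "plasma", na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Histogram of activation barriers in a network
#'
#' @param network a `reaction_network`.
#' @param binwidth histogram bin width in kcal/mol.
#' @return a ggplot object.
#' @export
plot_barrier_distribution <- function(network, binwidth = 5) {
  ggplot2::ggplot(network$edges,
                  ggplot2::aes(x = .data$delta_g_forward)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            color = "white", boundary = 0) +
    ggplot2::labs(x = expression(Delta * G^"‡" ~ "(kcal/mol)"),
                  y = "reactions") +
    ggplot2::theme_minimal()
}

#' Plot per-reactant performance statistics
#'
#' Success and intended rates per reactant, the per-reactant analogue of the
#' headline efficiency numbers.
#'
#' @param object a `network_statistics` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.network_statistics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_reactant,
                              c("success_rate", "intended_rate"),
                              names_to = "statistic", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reactant_key, y = .data$rate,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "reactant", y = "rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
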