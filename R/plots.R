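#' Plot a ceRNA network
#'
#' Draws the tripartite lncRNA--miRNA--mRNA network with a force-directed
#' layout: shared-miRNA edges link each pair member to its miRNAs, node
#' shape encodes the RNA class.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cerna_network
#' @export
autoplot.cerna_network <- function(object, ...) {
  flat <- flatten_pairs(object$network)
  if (nrow(flat) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
        ggplot2::theme_void()
    )
  }
  g <- pairs_to_igraph(flat)
  xy <- local({
    # fixed layout without disturbing the caller's RNG stream
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(1)
    igraph::layout_with_fr(g)
  })
  nodes <- tibble(
    name = igraph::V(g)$name,
    type = igraph::V(g)$type,
    x = xy[, 1], y = xy[, 2]
  )
  ed <- igraph::as_data_frame(g, what = "edges") |>
    left_join(nodes, by = c(from = "name")) |>
    left_join(nodes, by = c(to = "name"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to,
                   linetype = .data$kind),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type,
                   colour = .data$type),
      size = 3
    ) +
    ggplot2::scale_shape_manual(
      values = c(lncRNA = 18, miRNA = 16, mRNA = 15)
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(shape = "RNA class", colour = "RNA class",
                  linetype = "edge")
}

#' Volcano plot of differential-expression results
#'
#' @param object A `cerna_de` tibble from [run_de_analysis()].
#' @param ... Unused.
#' @return A ggplot object, faceted by comparison.
#' @method autoplot cerna_de
#' @export
autoplot.cerna_de <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$log2_fc, y = -log10(.data$p),
                 colour = .data$is_de)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "called DE") +
    ggplot2::theme_minimal()
}

#' Bar chart of network membership per comparison
#'
#' @param network A `cerna_network`.
#' @return A ggplot object.
#' @export
plot_network_summary <- function(network) {
  network$summary |>
    filter(.data$comparison != "overall") |>
    pivot_longer(c("n_pairs", "n_mrnas", "n_mirnas", "n_lncrnas"),
                 names_to = "quantity", values_to = "count") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$comparison, y = .data$count,
                                 fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
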