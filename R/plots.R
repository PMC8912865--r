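#' Plot a soft-power scan
#'
#' Two facets: the signed scale-free fit index against the candidate power
#' (with the target as a dashed line and the chosen power highlighted) and
#' the mean connectivity, which must decrease as the power grows.
#'
#' @param object A [pick_soft_power()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot softpower_scan
#' @export
autoplot.softpower_scan <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    df[c("power", "signed_r2", "mean_k")],
    cols = c("signed_r2", "mean_k"),
    names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("signed_r2", "mean_k"),
                        labels = c("signed scale-free fit R²",
                                   "mean connectivity"))
  targets <- data.frame(metric = levels(long$metric)[1],
                        value = attr(object, "r2_target"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(data = targets, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", color = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "soft power β", y = NULL)
  ch <- chosen_power(object)
  if (!is.na(ch)) {
    p <- p + ggplot2::geom_vline(xintercept = ch, linetype = "dotted",
                                 color = "blue")
  }
  p
}

#' Plot an HRR network
#'
#' Draws the network with a deterministic Fruchterman-Reingold layout
#' (seeded), edge opacity by band weight, and nodes colored by module when
#' labels are present.
#'
#' @param object An `hrr_network`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hrr_network
#' @export
autoplot.hrr_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes[match(igraph::V(g)$name, object$nodes$gene_id), ,
                        drop = FALSE]
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  coords <- stats::setNames(seq_len(nrow(nodes)), nodes$gene_id)
  edges <- object$edges
  seg <- data.frame(
    x = nodes$x[coords[edges$gene_a]], y = nodes$y[coords[edges$gene_a]],
    xend = nodes$x[coords[edges$gene_b]], yend = nodes$y[coords[edges$gene_b]],
    band_weight = edges$band_weight)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       alpha = .data$band_weight),
                          color = "grey50") +
    ggplot2::scale_alpha(range = c(0.2, 0.9), guide = "none") +
    ggplot2::theme_void()
  if ("module" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 color = factor(.data$module)), size = 2) +
      ggplot2::labs(color = "module")
  } else {
    p <- p + ggplot2::geom_point(data = nodes,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 size = 2)
  }
  p
}

#' Heatmap of regulator-to-target geodesic statistics
#'
#' @param geo Long tibble from [regulator_target_geodesics()].
#' @param value Which statistic to fill by: `"distance"` (geodesic length)
#'   or `"n_geodesics"` (number of distinct shortest paths).
#' @return A ggplot object; unreachable pairs are shown in grey.
#' @export
plot_geodesic_heatmap <- function(geo, value = c("distance", "n_geodesics")) {
  value <- match.arg(value)
  ggplot2::ggplot(geo, ggplot2::aes(x = .data$target, y = .data$regulator,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(low = "#f7f4f9", high = "#67001f",
                                 na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of a functional-category tally
#'
#' @param tally Tibble from [category_tally()].
#' @return A ggplot object.
#' @export
plot_category_tally <- function(tally) {
  ggplot2::ggplot(tally, ggplot2::aes(x = stats::reorder(.data$value, .data$n_genes),
                                      y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot module sizes
#' @param assignment A [cut_modules()] result.
#' @return A ggplot object (bar chart of module sizes, unassigned excluded).
#' @export
plot_module_sizes <- function(assignment) {
  sizes <- module_sizes(assignment)
  df <- data.frame(module = factor(names(sizes), levels = names(sizes)),
                   size = as.integer(sizes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col(fill = "#4d9221") +
    ggplot2::labs(x = "module", y = "genes") +
    ggplot2::theme_minimal()
}
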