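#' @method autoplot lipid_model
#' @export
autoplot.lipid_model <- function(object, ...) {
  df <- tibble(score = object$fitted,
               group = object$levels[object$y01 + 1])
  if (inherits(object, "lipid_opls") && object$n_orthogonal >= 1) {
    df$orthogonal <- object$ortho_scores[, 1]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$orthogonal,
                                          colour = .data$group)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "predictive score", y = "orthogonal score (1)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$group,
                                          colour = .data$group)) +
      ggplot2::geom_jitter(height = 0.1, width = 0) +
      ggplot2::labs(x = "model score", y = NULL)
  }
  p + ggplot2::theme_minimal() + ggplot2::labs(colour = NULL)
}

#' Loading plot of a discriminant model
#'
#' Features arranged by their loading on the predictive component:
#' displacement from zero measures importance, its direction marks the
#' group in which the feature is elevated.
#' @param model A fitted `lipid_model`.
#' @export
plot_loadings <- function(model) {
  td <- tidy(model)
  td$term <- factor(td$term, levels = td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$loading, y = .data$term)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "predictive loading", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot pcn
#' @export
autoplot.pcn <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges |>
    left_join(nodes[, c("name", "x", "y")], by = c(from = "name")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes[, c("name", "x", "y")], by = c(to = "name"))
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$sign),
      alpha = 0.5)
  }
  for (ell in object$ellipses) {
    if (length(ell$center) == 2) {
      p <- p + ggplot2::geom_path(data = ellipse_boundary(ell),
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  linetype = "dotted")
    }
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$role)) +
    ggplot2::scale_colour_manual(values = c(positive = "orange",
                                            negative = "steelblue")) +
    ggplot2::labs(title = paste0("Parameter connectivity network (",
                                 object$group, ", p < ",
                                 object$p_threshold, ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot pathway_graph
#' @export
autoplot.pathway_graph <- function(object, ...) {
  # circle layout keyed by class then name keeps related nodes adjacent
  nodes <- arrange(object$nodes, .data$chem_class, .data$name)
  ang <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
  nodes$x <- cos(ang); nodes$y <- sin(ang)
  edges <- object$edges |>
    left_join(nodes[, c("name", "x", "y")], by = c(substrate = "name")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes[, c("name", "x", "y")], by = c(product = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   colour = .data$status, linewidth = .data$width),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size, fill = .data$status),
                        shape = 21) +
    ggplot2::scale_colour_manual(values = c(increased = "orange",
                                            decreased = "steelblue",
                                            `not-significant` = "grey60",
                                            `no-ratio` = "grey85")) +
    ggplot2::scale_fill_manual(values = c(increased = "orange",
                                          decreased = "steelblue",
                                          `not-significant` = "grey60")) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Heatmap of two-group Spearman correlations
#' @param pair A [spearman_pair()] result.
#' @param p_mask Significance mask threshold.
#' @export
plot_correlation_heatmap <- function(pair, p_mask = 0.05) {
  m <- correlation_heatmap_matrix(pair, p_mask)
  df <- as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal")
  names(df) <- c("var1", "var2", "rho")
  df$var1 <- factor(df$var1, levels = pair$variables)
  df$var2 <- factor(df$var2, levels = rev(pair$variables))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "orange", na.value = "grey95",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = paste0(pair$groups[1], " (upper)"),
                  y = paste0(pair$groups[2], " (lower)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
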