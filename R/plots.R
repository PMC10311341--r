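# ggplot2 views of the package's result types.  Layouts are deterministic
# (families on a circle, ordered alphabetically) so repeated plots of the
# same graph are identical.

circle_layout <- function(families) {
  families <- sort(families)
  k <- length(families)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k
  tibble(family = families, x = cos(ang), y = sin(ang))
}

#' Plot a similarity graph
#'
#' Families are placed on a circle; solid and dotted edges follow the
#' participation status and each edge is labeled with its average RMSD,
#' average aligned length and minimum participation percentage.
#'
#' @param object a `similarity_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.similarity_graph <- function(object, ...) {
  lay <- circle_layout(object$nodes$family)
  nodes <- left_join(object$nodes, lay, by = "family")
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0L) {
    e <- object$edges %>%
      left_join(rename(lay, xa = "x", ya = "y"), by = c(family_a = "family")) %>%
      left_join(rename(lay, xb = "x", yb = "y"), by = c(family_b = "family"))
    e$label <- edge_label(e)
    e <- mutate(e, mx = (.data$xa + .data$xb) / 2,
                my = (.data$ya + .data$yb) / 2)
    p <- p +
      ggplot2::geom_segment(
        data = e,
        ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                     yend = .data$yb, linetype = .data$status),
        colour = "grey40") +
      ggplot2::geom_label(
        data = e,
        ggplot2::aes(x = .data$mx, y = .data$my, label = .data$label),
        size = 2.6, label.size = 0) +
      ggplot2::scale_linetype_manual(
        values = c(solid = "solid", dotted = "dotted"))
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 10, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   label = sprintf("%s\n(%d)", .data$family,
                                   .data$n_instances)),
      size = 3) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Motif family similarity (%s mode)",
                                  object$mode),
                  subtitle = sprintf("RMSD cutoff %g Å, solid at ≥ %g%% participation",
                                     object$parameters$rmsd_cutoff,
                                     object$parameters$pct_threshold)) +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot.similarity_graph
#' @export
autoplot.motif_comparison <- function(object, ...) {
  autoplot(object$graph, ...)
}

#' Plot a PCA projection of motif features
#'
#' @param projection output of [pca_projection()].
#' @return a ggplot object.
#' @export
plot_pca_projection <- function(projection) {
  ggplot2::ggplot(projection,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$family)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Motif features, first two principal components")
}

#' Plot per-run cross-validation metrics
#'
#' @param object a `cv_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  runs <- tidy(object)
  long <- tidyr::pivot_longer(runs,
                              cols = c("accuracy", "sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  long <- filter(long, is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("Cross-validation metrics: %s", object$model),
                  y = "percent", x = NULL)
}
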