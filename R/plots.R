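#' Plot the dynamical manifold
#'
#' Landscape `phi(y) = -ln P(y)` as a filled raster with cells overlaid at
#' their membership-weighted positions.
#'
#' @param object an `stt_manifold`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stt_manifold <- function(object, ...) {
  g <- object$grid
  df <- data.frame(x = rep(g$x, times = length(g$y)),
                   y = rep(g$y, each = length(g$x)),
                   phi = as.vector(g$phi))
  cells <- data.frame(x = object$y[, 1], y = object$y[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$phi)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$phi),
                          colour = "white", alpha = 0.4, bins = 12) +
    ggplot2::geom_point(data = cells, size = 0.3, alpha = 0.4,
                        colour = "black") +
    ggplot2::scale_fill_viridis_c(name = expression(phi)) +
    ggplot2::labs(x = "dim 1", y = "dim 2",
                  title = "Dynamical manifold") +
    ggplot2::theme_minimal()
}

#' Plot memberships and entropy on an embedding
#'
#' @param fit an `stt_fit`.
#' @param embedding optional cells x 2 coordinates (defaults to the fit's
#'   top-2 joint principal components).
#' @param colour `"attractor"` or `"entropy"`.
#' @return a ggplot object.
#' @export
plot_membership <- function(fit, embedding = NULL,
                            colour = c("attractor", "entropy")) {
  colour <- match.arg(colour)
  if (is.null(embedding)) embedding <- fit$pca$scores[, 1:2]
  df <- data.frame(x = embedding[, 1], y = embedding[, 2],
                   attractor = factor(fit$membership$hard),
                   entropy = fit$membership$entropy)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = "PC1", y = "PC2") + ggplot2::theme_minimal()
  if (colour == "attractor")
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$attractor), size = 0.6)
  else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$entropy), size = 0.6) +
      ggplot2::scale_colour_viridis_c()
}

#' Plot projected velocity streamline arrows
#'
#' @param fit an `stt_fit`.
#' @param arrows cells x 2 matrix from [project_streamlines()].
#' @param embedding optional cells x 2 coordinates.
#' @param subsample plot at most this many arrows.
#' @return a ggplot object.
#' @export
plot_streamlines <- function(fit, arrows, embedding = NULL,
                             subsample = 500) {
  if (is.null(embedding)) embedding <- fit$pca$scores[, 1:2]
  n <- nrow(embedding)
  idx <- if (n > subsample) seq(1, n, length.out = subsample) else seq_len(n)
  idx <- unique(round(idx))
  sc <- 0.1 * max(apply(embedding, 2, function(v) diff(range(v)))) /
    max(sqrt(rowSums(arrows^2)) + 1e-12)
  df <- data.frame(x = embedding[idx, 1], y = embedding[idx, 2],
                   xend = embedding[idx, 1] + sc * arrows[idx, 1],
                   yend = embedding[idx, 2] + sc * arrows[idx, 2],
                   attractor = factor(fit$membership$hard[idx]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$xend, yend = .data$yend,
                                       colour = .data$attractor),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
                          linewidth = 0.3) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
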