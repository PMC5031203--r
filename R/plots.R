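#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot incremental net-benefit distributions
#'
#' Density of each incremental contrast `NB_t - NB_0`; mass on both sides
#' of zero is what makes the decision uncertain and the value of
#' information positive.
#'
#' @param object a [psa_dataset].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.psa_dataset <- function(object, ...) {
  nb <- as.matrix(object$nb)
  inc <- nb[, -1, drop = FALSE] - nb[, 1]
  df <- tidyr::pivot_longer(
    tibble::as_tibble(inc), dplyr::everything(),
    names_to = "contrast", values_to = "incremental_nb")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$incremental_nb,
                                   colour = .data$contrast)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("incremental net benefit vs %s (k = %g)",
                              object$treatments[1], object$k),
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a finite-element mesh
#'
#' Triangulation with the inner and outer boundary rings; optionally
#' overlays the (projected) data points, which should sit strictly inside
#' the inner boundary.
#'
#' @param object an [build_mesh()] mesh.
#' @param points optional `n x 2` matrix of data points to overlay.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.evppi_mesh <- function(object, points = NULL, ...) {
  V <- object$vertices; Tm <- object$triangles
  edges <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  seg <- tibble::tibble(x = V[edges[, 1], 1], y = V[edges[, 1], 2],
                        xend = V[edges[, 2], 1], yend = V[edges[, 2], 2])
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.1, colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "z1", y = "z2")
  ir <- object$inner_rect
  rect <- tibble::tibble(xmin = ir$x[1], xmax = ir$x[2],
                         ymin = ir$y[1], ymax = ir$y[2])
  p <- p + ggplot2::geom_rect(
    data = rect,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                 ymin = .data$ymin, ymax = .data$ymax),
    fill = NA, colour = "black", linewidth = 0.3, inherit.aes = FALSE)
  if (!is.null(points)) {
    dfp <- tibble::tibble(x = points[, 1], y = points[, 2])
    p <- p + ggplot2::geom_point(
      data = dfp, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "steelblue", size = 0.4, inherit.aes = FALSE)
  }
  p
}

#' Plot fitted net-benefit surface over the projected space
#'
#' Fitted values of an SPDE latent-model fit against the two projected
#' coordinates, the standard visual check that the surface is smooth and
#' the residual structure (if any) localized.
#'
#' @param object an [lgm_fit()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.spde_fit <- function(object, ...) {
  H <- object$H
  df <- tibble::tibble(z1 = H[, "z1"], z2 = H[, "z2"],
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, y = .data$z2,
                                   colour = .data$fitted)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "fitted\ncontrast")
}

#' Plot a monotonicity audit
#'
#' EVPPI estimates against nested focal-set size; a correct estimator
#' yields a (noisily) non-decreasing curve.
#'
#' @param object a [monotonicity_check()] report.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.monotonicity_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "focal-set size", y = "EVPPI estimate",
                  title = sprintf("method: %s", attr(object, "method"))) +
    ggplot2::theme_minimal()
}
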