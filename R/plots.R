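#' Plot a density field
#'
#' Raster view of the cell density on the unit square; monolayer in dark,
#' cell-free wound in light.
#'
#' @param field A [density_field()].
#' @return A ggplot object.
#' @export
plot_density_field <- function(field) {
  m <- nrow(field$values)
  g <- (seq_len(m) - 1) * field$h
  df <- tibble::tibble(
    x = rep(g, times = m), y = rep(g, each = m),
    rho = as.vector(field$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$rho)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", fill = expression(rho),
                  title = sprintf("t = %.3g", field$t)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.density_field <- function(object, ...) plot_density_field(object)

#' @export
autoplot.wound_sim <- function(object, ...) {
  df <- tidy.wound_sim(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$wound_area)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "time (dimensionless)", y = "wound area fraction") +
    ggplot2::theme_minimal()
  if (isTRUE(object$closed)) {
    p <- p + ggplot2::geom_vline(xintercept = object$closure_time,
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$r, .data$C)) +
    ggplot2::geom_hline(yintercept = 0.37, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Delta * r ~ (mu * m)),
                  y = expression(C(Delta * r))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.von_mises_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(-pi, pi, length.out = 361))
  grid$density <- von_mises_pdf(grid$x, object$mu, object$kappa)
  ggplot2::ggplot() +
    ggplot2::geom_col(data = object$histogram,
                      ggplot2::aes(.data$mid, .data$density),
                      width = 2 * pi / nrow(object$histogram),
                      fill = "grey80") +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$density),
                       color = "firebrick") +
    ggplot2::labs(x = "direction relative to wound normal (rad)",
                  y = "probability density",
                  title = sprintf("von Mises fit: kappa = %.2f", object$kappa)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  s <- tidy.sweep_result(object)
  long <- tidyr::pivot_longer(
    s, c("closure_mean", "edge_length_mean"),
    names_to = "metric", values_to = "mean")
  long$sem <- ifelse(long$metric == "closure_mean", s$closure_sem[
    match(long$value, s$value)], s$edge_length_sem[match(long$value, s$value)])
  long$metric <- ifelse(long$metric == "closure_mean",
                        "normalized wound closure", "normalized edge length")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = unique(s$parameter), y = NULL) +
    ggplot2::theme_minimal()
}
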