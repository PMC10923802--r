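#' Plotting helpers
#'
#' ggplot2 views of the core result types: MSD curves (log-log), rate
#' profiles with the fitted crowding curve, Phillies fits, and relaxation
#' trajectories. Numerical tables are the contract; these are convenience
#' views.
#'
#' @name plots
NULL

#' Plot an MSD curve on log-log axes
#'
#' @param msd an MSD tibble from [msd_ensemble()]; a `phi` column maps to
#'   colour.
#' @return a ggplot.
#' @export
plot_msd <- function(msd) {
  p <- ggplot2::ggplot(msd, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2))
  if ("phi" %in% names(msd)) {
    p <- p + ggplot2::aes(colour = factor(.data$phi)) +
      ggplot2::labs(colour = expression(phi))
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(MSD ~ (mu * m^2)))
}

#' Plot a rate profile and (optionally) a fitted crowding curve
#'
#' @param data a rate-profile tibble (`phi`, `rate` or `normalized_rate`).
#' @param fit an optional `rate_model_fit` overlaid as a curve.
#' @return a ggplot.
#' @export
plot_rate_profile <- function(data, fit = NULL) {
  rate_col <- if ("normalized_rate" %in% names(data)) "normalized_rate" else "rate"
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$phi, y = .data[[rate_col]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "relative cytoplasmic concentration (x)",
                  y = "normalized rate")
  if (!is.null(fit)) {
    grid <- tibble::tibble(phi = seq(min(data$phi), max(data$phi), length.out = 200))
    grid$rate <- predict(fit, grid$phi)
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$phi, y = .data$rate),
      colour = "firebrick"
    )
  }
  p
}

#' @export
autoplot.rate_model_fit <- function(object, phi_max = 2.5, ...) {
  grid <- tibble::tibble(phi = seq(0, phi_max, length.out = 300))
  grid$rate <- predict(object, grid$phi)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$phi_opt, linetype = "dashed") +
    ggplot2::labs(x = "relative cytoplasmic concentration (x)",
                  y = "relative rate")
}

#' @export
autoplot.phillies_fit <- function(object, phi_max = 2, ...) {
  grid <- tibble::tibble(phi = seq(0, phi_max, length.out = 200))
  grid$D <- predict_diffusion(object, grid$phi)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi, y = .data$D)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative cytoplasmic concentration (x)",
                  y = expression(D ~ (mu * m^2 / s)))
}

#' Plot a relaxation trajectory of the homeostasis model
#'
#' @param traj a tibble from [simulate_relaxation()] (`time_h`, `phi`).
#' @return a ggplot.
#' @export
plot_relaxation <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_h, y = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "relative cytoplasmic concentration (x)")
}
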