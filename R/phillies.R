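#' Phillies's-law scaling of diffusion with cytoplasmic concentration
#'
#' In macromolecule solutions, probe diffusion follows the empirical
#' relation `D(phi) = D0 * exp(-mu * phi)`, where `phi` is the relative
#' cytoplasmic concentration (1x = undiluted extract), `D0` the coefficient
#' in protein-free filtrate, and `mu` a scaling factor that grows with probe
#' size. A second, linear relation `mu = a * d_p` links the scaling factor
#' to the probe diameter; `a` (1/nm) feeds the crowding rate model.
#'
#' @name phillies
NULL

#' Fit Phillies's law to diffusion-vs-concentration data
#'
#' Ordinary least squares of `log(D)` on `phi`; `D0 = exp(intercept)` and
#' `mu = -slope`. Log-space fitting matches the exponential form and
#' stabilizes the roughly 100-fold dynamic range of `D` across a 0x-2x
#' dilution series. Standard errors come from the linear fit (delta method
#' for `D0`).
#'
#' @param data a data frame with columns `phi` and `D_um2_s` (at least two
#'   distinct `phi`, all `D` positive). Filtrate points (`phi = 0`) are
#'   included like any other.
#' @return a `phillies_fit` object with fields `D0`, `mu`, `se_D0`,
#'   `se_mu`, `r2`, `phi_range`, `n`.
#' @export
fit_phillies <- function(data) {
  if (!all(c("phi", "D_um2_s") %in% names(data))) {
    abort("`data` must have columns `phi` and `D_um2_s`.")
  }
  phi <- data$phi
  D <- data$D_um2_s
  if (dplyr::n_distinct(phi) < 2) abort("Need at least 2 distinct `phi` values.")
  if (any(!is.finite(D)) || any(D <= 0)) {
    abort("All diffusion coefficients must be positive (log-space fit).")
  }
  fit <- lm(log(D) ~ phi)
  s <- suppressWarnings(summary(fit))$coefficients
  D0 <- exp(unname(coef(fit)[1]))
  structure(list(
    D0 = D0,
    mu = -unname(coef(fit)[2]),
    se_D0 = D0 * s[1, 2],
    se_mu = s[2, 2],
    r2 = suppressWarnings(summary(fit))$r.squared,
    phi_range = range(phi),
    n = length(phi)
  ), class = "phillies_fit")
}

#' @export
print.phillies_fit <- function(x, ...) {
  cat("<phillies_fit>  D(phi) = D0 * exp(-mu * phi)\n")
  cat(sprintf("  D0 = %.4g um^2/s (se %.3g)\n", x$D0, x$se_D0))
  cat(sprintf("  mu = %.4g (se %.3g);  log-space R^2 = %.4f;  n = %d\n",
              x$mu, x$se_mu, x$r2, x$n))
  invisible(x)
}

#' @export
tidy.phillies_fit <- function(x, ...) {
  tibble::tibble(
    term = c("D0", "mu"),
    estimate = c(x$D0, x$mu),
    std.error = c(x$se_D0, x$se_mu)
  )
}

#' @export
glance.phillies_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n,
                 phi_min = x$phi_range[1], phi_max = x$phi_range[2])
}

#' Predict diffusion coefficients from a Phillies fit
#'
#' Evaluates `D0 * exp(-mu * phi)`.
#'
#' @param fit a `phillies_fit`.
#' @param phi relative cytoplasmic concentrations (any non-negative reals).
#' @return predicted diffusion coefficients, um^2/s.
#' @export
predict_diffusion <- function(fit, phi) {
  stopifnot(inherits(fit, "phillies_fit"))
  fit$D0 * exp(-fit$mu * phi)
}

#' @export
predict.phillies_fit <- function(object, phi, ...) predict_diffusion(object, phi)

#' Fit the linear size scaling of the Phillies factor
#'
#' Least-squares fit of `mu = a * d_p` across beads of different measured
#' (apparent) diameter. Through the origin by default, since the crowding
#' rate model substitutes `mu = a * d_p` with no offset; `through_origin =
#' FALSE` adds a free intercept.
#'
#' @param data a data frame with columns `mu` and `diameter_nm` (at least
#'   one bead; >= 2 for the intercept mode).
#' @param through_origin constrain the line through the origin (default).
#' @return a `size_scaling_fit` with fields `a` (1/nm), `se_a`,
#'   `intercept`, `diameters`, `n`.
#' @export
fit_size_scaling <- function(data, through_origin = TRUE) {
  if (!all(c("mu", "diameter_nm") %in% names(data))) {
    abort("`data` must have columns `mu` and `diameter_nm`.")
  }
  mu <- data$mu
  d <- data$diameter_nm
  if (length(mu) < 1 || (!through_origin && length(mu) < 2)) {
    abort("Not enough beads for the requested fit.")
  }
  if (through_origin && length(mu) == 1) {
    # one-point through-origin fit is exact
    return(structure(list(
      a = mu / d, se_a = NA_real_, intercept = 0,
      diameters = d, n = 1L
    ), class = "size_scaling_fit"))
  }
  fit <- if (through_origin) lm(mu ~ 0 + d) else lm(mu ~ d)
  s <- suppressWarnings(summary(fit))$coefficients
  idx <- if (through_origin) 1 else 2
  structure(list(
    a = unname(coef(fit)[idx]),
    se_a = s[idx, 2],
    intercept = if (through_origin) 0 else unname(coef(fit)[1]),
    diameters = d,
    n = length(mu)
  ), class = "size_scaling_fit")
}

#' @export
print.size_scaling_fit <- function(x, ...) {
  cat("<size_scaling_fit>  mu = a * d_p\n")
  cat(sprintf("  a = %.4g nm^-1 (se %.3g); intercept %.3g; n = %d beads\n",
              x$a, x$se_a, x$intercept, x$n))
  invisible(x)
}

#' @export
tidy.size_scaling_fit <- function(x, ...) {
  tibble::tibble(term = "a", estimate = x$a, std.error = x$se_a)
}
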