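#' Biphasic crowding rate model
#'
#' Under mass-action kinetics with both enzyme and substrate proportional
#' to the relative cytoplasmic concentration `phi`, and a diffusion-limited
#' association rate that falls with crowding following Phillies's law with
#' `mu = a * d_p`, the reaction velocity relative to its 1x value is
#'
#' `V(phi) = phi^2 * exp(-a * d_p * (phi - 1))`
#'
#' a biphasic curve whose maximum sits at `phi* = 2 / (a * d_p)`: the
#' larger the macromolecular diameter `d_p`, the lower the optimal
#' concentration. With `a` fixed from bead-diffusion measurements
#' (0.018 nm^-1), `d_p` is the single adjustable parameter.
#'
#' @name rate-model
NULL

#' Crowding rate law
#'
#' Evaluates `scale * phi^2 * exp(-a * d_p * (phi - 1))`; with
#' `scale = 1` the value at `phi = 1` is exactly 1 (rates normalized to the
#' 1x extract).
#'
#' @param phi relative cytoplasmic concentration(s), >= 0.
#' @param d_p macromolecular diameter, nm.
#' @param a viscosity scaling factor, 1/nm (default 0.018).
#' @param scale amplitude (default 1).
#' @return relative reaction rate(s).
#' @export
eq2_rate <- function(phi, d_p, a = 0.018, scale = 1) {
  if (any(phi < 0)) abort("`phi` must be >= 0.")
  scale * phi^2 * exp(-a * d_p * (phi - 1))
}

#' Fit the macromolecular diameter to a normalized rate profile
#'
#' Unweighted nonlinear least squares of the crowding rate law to pooled
#' replicate rates, with `a` fixed and (by default) the amplitude fixed at
#' 1 because the data are normalized to the 1x rate. The starting value
#' `d_p = 2 / (a * phi_peak)` is derived from the grid argmax of the mean
#' profile, so the fit is self-starting. Standard error of `d_p` comes from
#' the fit covariance; the optimum `phi* = 2 / (a * d_p)` and its
#' delta-method standard error are attached.
#'
#' @param data a rate-profile tibble with columns `phi` and `rate`
#'   (optionally `normalized_rate`, preferred when present); >= 4 distinct
#'   `phi` required.
#' @param a fixed viscosity scaling factor, 1/nm.
#' @param free_scale also fit a free amplitude (default `FALSE`).
#' @param weights optional per-point weights for weighted least squares.
#' @return a `rate_model_fit` with fields `d_p`, `se_dp`, `a`, `scale`,
#'   `se_scale`, `r2`, `phi_opt`, `se_phi_opt`, `n`.
#' @export
fit_dp <- function(data, a = 0.018, free_scale = FALSE, weights = NULL) {
  if (!"phi" %in% names(data)) abort("`data` must have a `phi` column.")
  rate_col <- if ("normalized_rate" %in% names(data)) "normalized_rate" else "rate"
  if (!rate_col %in% names(data)) abort("`data` must have a `rate` column.")
  df <- tibble::tibble(phi = data$phi, rate = data[[rate_col]])
  df <- df[is.finite(df$phi) & is.finite(df$rate), ]
  if (dplyr::n_distinct(df$phi) < 4) abort("Need >= 4 distinct `phi` values.")
  mean_profile <- df |>
    dplyr::group_by(.data$phi) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  phi_peak <- mean_profile$phi[which.max(mean_profile$rate)]
  dp0 <- 2 / (a * phi_peak)
  w <- weights %||% rep(1, nrow(df))
  fit <- tryCatch(
    {
      if (free_scale) {
        minpack.lm::nlsLM(
          rate ~ scale * phi^2 * exp(-a * d_p * (phi - 1)),
          data = df, start = list(d_p = dp0, scale = 1),
          lower = c(d_p = 1e-6, scale = 1e-6), weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 500)
        )
      } else {
        minpack.lm::nlsLM(
          rate ~ phi^2 * exp(-a * d_p * (phi - 1)),
          data = df, start = list(d_p = dp0),
          lower = c(d_p = 1e-6), weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 500)
        )
      }
    },
    error = function(e) {
      abort(paste0("Rate-model fit did not converge (start d_p = ",
                   signif(dp0, 4), " nm): ", conditionMessage(e)))
    }
  )
  est <- coef(fit)
  s <- suppressWarnings(summary(fit))$coefficients
  d_p <- est[["d_p"]]
  se_dp <- s["d_p", 2]
  scale <- if (free_scale) est[["scale"]] else 1
  se_scale <- if (free_scale) s["scale", 2] else 0
  pred <- predict(fit)
  ss_res <- sum(w * (df$rate - pred)^2)
  ss_tot <- sum(w * (df$rate - mean(df$rate))^2)
  opt <- optimal_phi(d_p, a = a, se_dp = se_dp)
  structure(list(
    d_p = d_p, se_dp = se_dp, a = a,
    scale = scale, se_scale = se_scale,
    r2 = 1 - ss_res / ss_tot,
    phi_opt = opt$phi_opt, se_phi_opt = opt$se_phi_opt,
    n = nrow(df), free_scale = free_scale
  ), class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat("<rate_model_fit>  V = scale * phi^2 * exp(-a d_p (phi - 1))\n")
  cat(sprintf("  d_p = %.4g nm (se %.3g), a = %.4g nm^-1 (fixed)\n",
              x$d_p, x$se_dp, x$a))
  if (x$free_scale) cat(sprintf("  scale = %.4g (se %.3g)\n", x$scale, x$se_scale))
  cat(sprintf("  phi* = %.4g (se %.3g);  R^2 = %.4f;  n = %d\n",
              x$phi_opt, x$se_phi_opt, x$r2, x$n))
  invisible(x)
}

#' @export
tidy.rate_model_fit <- function(x, ...) {
  terms <- c("d_p", if (x$free_scale) "scale", "phi_opt")
  tibble::tibble(
    term = terms,
    estimate = c(x$d_p, if (x$free_scale) x$scale, x$phi_opt),
    std.error = c(x$se_dp, if (x$free_scale) x$se_scale, x$se_phi_opt)
  )
}

#' @export
glance.rate_model_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n, a = x$a)
}

#' @export
predict.rate_model_fit <- function(object, phi, ...) {
  eq2_rate(phi, d_p = object$d_p, a = object$a, scale = object$scale)
}

#' Optimal cytoplasmic concentration of the crowding rate law
#'
#' Setting `dV/dphi = 0` for `V = phi^2 * exp(-a * d_p * (phi - 1))` gives
#' the closed form `phi* = 2 / (a * d_p)`. The standard error is first-order
#' propagation: `se(phi*) = phi* * se(d_p) / d_p`.
#'
#' @param d_p macromolecular diameter, nm (> 0).
#' @param a viscosity scaling factor, 1/nm (> 0).
#' @param se_dp optional standard error of `d_p`.
#' @return a one-row tibble with `phi_opt` and `se_phi_opt`.
#' @export
optimal_phi <- function(d_p, a = 0.018, se_dp = NULL) {
  if (any(d_p <= 0) || a <= 0) abort("`d_p` and `a` must be > 0.")
  phi_opt <- 2 / (a * d_p)
  se <- if (is.null(se_dp)) NA_real_ else phi_opt * se_dp / d_p
  tibble::tibble(phi_opt = phi_opt, se_phi_opt = se)
}

#' Coefficient of determination of a rate-model fit on a profile
#'
#' `R^2 = 1 - SS_res / SS_tot` on the normalized-rate scale with all
#' replicates pooled.
#'
#' @param fit a `rate_model_fit`.
#' @param data a rate-profile tibble (columns `phi` and `rate` /
#'   `normalized_rate`).
#' @return R-squared.
#' @export
r_squared <- function(fit, data) {
  stopifnot(inherits(fit, "rate_model_fit"))
  rate_col <- if ("normalized_rate" %in% names(data)) "normalized_rate" else "rate"
  y <- data[[rate_col]]
  pred <- predict(fit, data$phi)
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Michaelis-Menten variant of the crowding rate law
#'
#' Extension of the mass-action law to a saturable enzyme: enzyme and
#' substrate are both proportional to `phi`, and the diffusion-limited part
#' of the Michaelis constant scales inversely with the Phillies factor
#' `exp(-a * d_p * (phi - 1))`. With `g(phi)` that factor,
#' `s` the saturation `S / K_M` at `phi = 1`, and `f` the fraction of the
#' binding resistance that is diffusion-limited at `phi = 1`:
#'
#' `V(phi) proportional to phi * (phi s) / (f / g(phi) + (1 - f) + phi s)`
#'
#' normalized so `V(1) = 1`. In the limit `s -> 0`, `f = 1`, this reduces
#' exactly to [eq2_rate()]'s `phi`-dependence; with `f = 0` the velocity is
#' independent of `a * d_p` (pure reaction control); increasing `s` shifts
#' the optimum.
#'
#' @param phi relative cytoplasmic concentration(s), >= 0.
#' @param d_p macromolecular diameter, nm.
#' @param a viscosity scaling factor, 1/nm.
#' @param saturation `S / K_M` at `phi = 1`, >= 0 (0 is the
#'   far-from-saturation limit, taken analytically).
#' @param diffusion_control fraction of binding resistance that is
#'   diffusion-limited at `phi = 1`, in [0, 1].
#' @return relative reaction rate(s), normalized to `V(1) = 1`.
#' @export
mm_rate <- function(phi, d_p, a = 0.018, saturation = 0, diffusion_control = 1) {
  if (any(phi < 0)) abort("`phi` must be >= 0.")
  if (saturation < 0) abort("`saturation` must be >= 0.")
  if (diffusion_control < 0 || diffusion_control > 1) {
    abort("`diffusion_control` must lie in [0, 1].")
  }
  g <- exp(-a * d_p * (phi - 1))
  f <- diffusion_control
  s <- saturation
  denom <- f / g + (1 - f)
  if (s == 0) {
    # far-from-saturation limit: V = phi^2 / (f/g + 1 - f), V(1) = 1 already
    return(phi^2 / denom)
  }
  raw <- phi^2 * s / (denom + phi * s)
  raw1 <- s / (1 + s)
  raw / raw1
}
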