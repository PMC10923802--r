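#' Concentration-homeostasis feedback model
#'
#' Because translation involves much larger machinery than degradation, its
#' optimal cytoplasmic concentration is lower; with both rate laws
#' normalized to 1 at `phi = 1`, any rise in concentration above 1x lowers
#' synthesis relative to degradation and any fall raises it, a negative
#' feedback with a stable set point at 1x. The minimal mass balance
#' consistent with that argument is
#'
#' `d phi / dt = gamma * (V_syn(phi) - V_deg(phi))`
#'
#' with both velocities given by the crowding rate law [eq2_rate()] and
#' `gamma` a single turnover time-scale (1/hour), anchored by default to
#' the 43 h median protein half-life (`gamma = log(2) / 43`).
#'
#' @name homeostasis
NULL

#' Build a homeostasis model from fitted diameters
#'
#' @param d_p_syn synthesis-machinery diameter, nm (default 104, the fitted
#'   translation value).
#' @param d_p_deg degradation-machinery diameter, nm (default 14, the
#'   fitted degradation value).
#' @param a viscosity scaling factor, 1/nm.
#' @param gamma turnover time scale, 1/hour (default `log(2) / 43`).
#' @return a `homeostasis_model`.
#' @export
homeostasis_model <- function(d_p_syn = 104, d_p_deg = 14, a = 0.018,
                              gamma = log(2) / 43) {
  if (d_p_syn <= 0 || d_p_deg <= 0) abort("Diameters must be positive.")
  if (a <= 0) abort("`a` must be positive.")
  if (gamma <= 0) abort("`gamma` must be positive.")
  structure(list(d_p_syn = d_p_syn, d_p_deg = d_p_deg, a = a, gamma = gamma),
            class = "homeostasis_model")
}

#' @export
print.homeostasis_model <- function(x, ...) {
  cat("<homeostasis_model>  d phi/dt = gamma (V_syn - V_deg)\n")
  cat(sprintf("  d_p_syn = %g nm, d_p_deg = %g nm, a = %g nm^-1, gamma = %.4g /h\n",
              x$d_p_syn, x$d_p_deg, x$a, x$gamma))
  invisible(x)
}

#' Net synthesis-minus-degradation flux
#'
#' `V_syn(phi) - V_deg(phi)`, both normalized to 1 at `phi = 1`, so the net
#' flux at `phi = 1` is exactly 0 by construction. The flux is
#' dimensionless; multiply by `gamma` for the time derivative.
#'
#' @param model a `homeostasis_model`.
#' @param phi relative cytoplasmic concentration(s), >= 0.
#' @return net flux value(s).
#' @export
net_flux <- function(model, phi) {
  stopifnot(inherits(model, "homeostasis_model"))
  eq2_rate(phi, d_p = model$d_p_syn, a = model$a) -
    eq2_rate(phi, d_p = model$d_p_deg, a = model$a)
}

#' Locate and classify steady states of the homeostasis model
#'
#' Scans `net_flux` for sign changes on a grid over `phi_range`, polishes
#' each root with [stats::uniroot()], and classifies stability from the
#' sign of the numerical derivative of `gamma * net_flux`: negative
#' derivative means perturbations decay (stable). `phi = 0` is reported as
#' a degenerate boundary equilibrium (both rate laws vanish there), kept
#' separate from interior steady states.
#'
#' @param model a `homeostasis_model`.
#' @param phi_range interval to scan (default `c(0.01, 20)`).
#' @param n_grid grid points for the sign scan.
#' @param tolerance root tolerance.
#' @return a tibble with columns `phi_ss`, `type` (`"interior"` /
#'   `"boundary"`), `stability` (`"stable"`, `"unstable"`, `"marginal"`),
#'   `decay_rate` (d(gamma * net_flux)/d phi at the root, 1/hour).
#' @export
find_steady_states <- function(model, phi_range = c(0.01, 20), n_grid = 2000,
                               tolerance = 1e-10) {
  stopifnot(inherits(model, "homeostasis_model"))
  grid <- seq(phi_range[1], phi_range[2], length.out = n_grid)
  f <- net_flux(model, grid)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (f[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (f[i] * f[i + 1] < 0) {
      r <- uniroot(function(p) net_flux(model, p), c(grid[i], grid[i + 1]),
                   tol = tolerance)
      roots <- c(roots, r$root)
    }
  }
  if (f[n_grid] == 0) roots <- c(roots, grid[n_grid])
  roots <- unique(round(roots, 10))
  h <- 1e-6
  classify <- function(p) {
    deriv <- model$gamma *
      (net_flux(model, p + h) - net_flux(model, max(p - h, 0))) /
      (p + h - max(p - h, 0))
    stab <- if (deriv < -1e-8) "stable" else if (deriv > 1e-8) "unstable" else "marginal"
    tibble::tibble(phi_ss = p, type = "interior", stability = stab,
                   decay_rate = deriv)
  }
  interior <- dplyr::bind_rows(lapply(roots, classify))
  boundary <- tibble::tibble(
    phi_ss = 0, type = "boundary", stability = "marginal",
    decay_rate = 0
  )
  dplyr::bind_rows(boundary, interior)
}

#' Simulate relaxation of the cytoplasmic concentration
#'
#' Integrates `d phi / dt = gamma * net_flux(phi)` with a fixed-step
#' classical 4th-order Runge-Kutta scheme. The step size is checked against
#' the linearized decay rate at the 1x set point
#' (`gamma * a * (d_p_deg - d_p_syn)`); a clearly unstable step is rejected
#' up front, and divergence during integration raises an error suggesting a
#' smaller `dt`.
#'
#' @param model a `homeostasis_model`.
#' @param phi0 initial relative concentration, > 0.
#' @param t_end integration horizon, hours.
#' @param dt time step, hours.
#' @return a tibble with columns `time_h`, `phi`.
#' @export
simulate_relaxation <- function(model, phi0, t_end = 400, dt = 0.1) {
  stopifnot(inherits(model, "homeostasis_model"))
  if (!is.finite(phi0) || phi0 <= 0) abort("`phi0` must be > 0.")
  if (dt <= 0 || t_end <= 0) abort("`dt` and `t_end` must be positive.")
  lambda <- model$gamma * model$a * (model$d_p_deg - model$d_p_syn)
  if (lambda < 0 && dt > 2.78 / abs(lambda)) {
    # RK4 real-axis stability limit |z| < 2.785
    abort(sprintf(
      "Step dt = %g h is unstable for the local decay rate %.3g /h; use dt <= %.3g.",
      dt, lambda, 2.78 / abs(lambda)
    ))
  }
  f <- function(p) model$gamma * net_flux(model, max(p, 0))
  n_steps <- ceiling(t_end / dt)
  phi <- numeric(n_steps + 1)
  phi[1] <- phi0
  p <- phi0
  for (i in seq_len(n_steps)) {
    k1 <- f(p)
    k2 <- f(p + dt / 2 * k1)
    k3 <- f(p + dt / 2 * k2)
    k4 <- f(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(p) || p > 1e6) {
      abort(sprintf(
        "Integration diverged at step %d; try a smaller dt (e.g. %g).",
        i, dt / 10
      ))
    }
    phi[i + 1] <- p
  }
  tibble::tibble(time_h = seq(0, by = dt, length.out = n_steps + 1), phi = phi)
}
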