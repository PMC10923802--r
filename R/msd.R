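#' Mean squared displacement and diffusion estimation
#'
#' Estimators for single-particle-tracking data: per-trajectory and
#' ensemble MSD curves, the anomalous diffusivity exponent alpha from
#' log-log regression, the effective diffusion coefficient from a short-lag
#' linear fit (`D_eff = MSD / (4 tau)` in two dimensions), and the
#' Stokes-Einstein hydrodynamic diameter.
#'
#' @name msd
NULL

# per-trajectory MSD from position vectors; n runs 1..n_max where n_max is
# the largest lag with at least one displacement term under the chosen
# convention. The default uses N - n - 1 terms (one fewer than the
# conventional N - n): the last overlapping displacement is dropped.
msd_single <- function(x, y, conventional = FALSE) {
  N <- length(x)
  n_terms_at <- function(n) if (conventional) N - n else N - n - 1
  n_max <- if (conventional) N - 1 else N - 2
  n <- seq_len(n_max)
  msd <- vapply(n, function(nn) {
    m <- n_terms_at(nn)
    i <- seq_len(m)
    dx <- x[i + nn] - x[i]
    dy <- y[i + nn] - y[i]
    sum(dx * dx + dy * dy) / m
  }, numeric(1))
  list(n = n, msd = msd, weight = vapply(n, n_terms_at, numeric(1)))
}

check_trajectory_cols <- function(data) {
  need <- c("particle_id", "frame", "x_um", "y_um")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Trajectory data must have columns ", paste(need, collapse = ", "),
      "; missing: ", paste(missing, collapse = ", "), "."
    ))
  }
  if (!all(is.finite(data$x_um)) || !all(is.finite(data$y_um))) {
    abort("Trajectory coordinates must be finite.")
  }
  invisible(TRUE)
}

resolve_frame_interval <- function(data, frame_interval) {
  dt <- frame_interval %||% attr(data, "frame_interval", exact = TRUE)
  if (is.null(dt)) {
    abort("Supply `frame_interval` (seconds); the data carry no frame-interval attribute.")
  }
  if (!is.finite(dt) || dt <= 0) abort("`frame_interval` must be positive.")
  dt
}

#' MSD curve of a single trajectory
#'
#' Computes the time-averaged mean squared displacement of one 2-D
#' trajectory at integer frame lags `n = 1 .. N - 2`, averaging the
#' `N - n - 1` overlapping squared displacements at each lag (the last
#' displacement is dropped; set `conventional = TRUE` for the usual
#' `N - n`-term average).
#'
#' @param data a trajectory tibble with columns `particle_id`, `frame`,
#'   `x_um`, `y_um` containing exactly one particle with at least 3 frames.
#' @param frame_interval sampling interval, seconds; defaults to the
#'   attribute attached by the simulators / readers.
#' @param conventional use the conventional `N - n`-term average instead of
#'   the `N - n - 1`-term estimator.
#' @return a tibble with columns `lag_s`, `msd_um2`, `weight` (number of
#'   displacement terms averaged).
#' @export
msd_trajectory <- function(data, frame_interval = NULL, conventional = FALSE) {
  check_trajectory_cols(data)
  dt <- resolve_frame_interval(data, frame_interval)
  if (dplyr::n_distinct(data$particle_id) != 1) {
    abort("`msd_trajectory()` expects a single particle; use `msd_ensemble()` for sets.")
  }
  data <- dplyr::arrange(data, .data$frame)
  if (any(diff(data$frame) != 1)) abort("Trajectory has gaps; frames must be consecutive.")
  N <- nrow(data)
  min_N <- if (conventional) 2 else 3
  if (N < min_N) abort("Trajectory too short: no valid lag exists.")
  res <- msd_single(data$x_um, data$y_um, conventional = conventional)
  tibble::tibble(lag_s = res$n * dt, msd_um2 = res$msd, weight = res$weight)
}

#' Ensemble MSD curve of a trajectory set
#'
#' Pools per-trajectory MSD curves across particles, weighting each
#' trajectory's value at lag `n` by its number of displacement terms
#' (`N_i - n - 1`) and dividing by the summed weights to give a weighted
#' mean (set `normalize = FALSE` to emit the raw weighted sum for audit).
#' Lags where no trajectory contributes are dropped. If the data carry a
#' `phi` column, the curve is computed separately per concentration.
#'
#' @inheritParams msd_trajectory
#' @param data a trajectory tibble; multiple particles allowed, optional
#'   `phi` grouping column.
#' @param normalize divide the weighted sum by the total weight (default);
#'   `FALSE` returns the unnormalized sum.
#' @return a tibble with columns `lag_s`, `msd_um2`, `weight` (total terms
#'   pooled), plus `phi` when present in the input.
#' @export
msd_ensemble <- function(data, frame_interval = NULL, normalize = TRUE,
                         conventional = FALSE) {
  check_trajectory_cols(data)
  dt <- resolve_frame_interval(data, frame_interval)
  if (nrow(data) == 0) abort("Empty trajectory set.")
  group_cols <- intersect("phi", names(data))
  per_group <- function(df) {
    curves <- df |>
      dplyr::group_by(.data$particle_id) |>
      dplyr::group_map(function(traj, key) {
        traj <- dplyr::arrange(traj, .data$frame)
        if (any(diff(traj$frame) != 1)) {
          abort(paste0("Trajectory ", key$particle_id, " has gaps."))
        }
        if (nrow(traj) < 3) return(NULL)
        res <- msd_single(traj$x_um, traj$y_um, conventional = conventional)
        tibble::tibble(n = res$n, msd = res$msd, weight = res$weight)
      }) |>
      dplyr::bind_rows()
    if (nrow(curves) == 0) abort("No trajectory long enough to contribute a lag.")
    curves |>
      dplyr::group_by(.data$n) |>
      dplyr::summarise(
        msd_um2 = if (normalize) {
          sum(.data$weight * .data$msd) / sum(.data$weight)
        } else {
          sum(.data$weight * .data$msd)
        },
        weight = sum(.data$weight),
        .groups = "drop"
      ) |>
      dplyr::transmute(lag_s = .data$n * dt, msd_um2 = .data$msd_um2,
                       weight = .data$weight)
  }
  if (length(group_cols) == 0) {
    per_group(data)
  } else {
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
      dplyr::group_modify(function(df, key) per_group(df)) |>
      dplyr::ungroup()
  }
}

new_diffusion_estimate <- function(fields) {
  structure(fields, class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat("<diffusion_estimate>\n")
  if (!is.na(x$alpha)) {
    cat(sprintf("  alpha  = %.4f (se %.4f), fit over lags <= %g s\n",
                x$alpha, x$se_alpha, x$fit_lag_max))
  }
  if (!is.na(x$D_eff)) {
    cat(sprintf("  D_eff  = %.4g um^2/s (se %.3g), intercept %.4g um^2 (%d points)\n",
                x$D_eff, x$se_D, x$intercept, x$n_points))
  }
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  rows <- list()
  if (!is.na(x$alpha)) {
    rows <- c(rows, list(tibble::tibble(
      term = "alpha", estimate = x$alpha, std.error = x$se_alpha
    )))
  }
  if (!is.na(x$D_eff)) {
    rows <- c(rows, list(tibble::tibble(
      term = c("D_eff", "intercept"),
      estimate = c(x$D_eff, x$intercept),
      std.error = c(x$se_D, x$se_intercept)
    )))
  }
  dplyr::bind_rows(rows)
}

#' Fit the anomalous diffusivity exponent alpha
#'
#' Ordinary least-squares slope of `log(MSD)` against `log(tau)` over lags
#' up to `max_lag` (default 1 s, the same time scale as the effective
#' diffusion fit). `alpha = 1` is normal diffusion, `alpha < 1`
#' subdiffusion, `alpha = 2` ballistic motion.
#'
#' @param msd an MSD tibble from [msd_trajectory()] or [msd_ensemble()].
#' @param max_lag largest lag (seconds) included in the fit.
#' @return a `diffusion_estimate` with fields `alpha`, `se_alpha`,
#'   `fit_lag_max`, `n_lags`.
#' @export
fit_anomalous_exponent <- function(msd, max_lag = 1.0) {
  keep <- msd$lag_s <= max_lag * (1 + .tol) & msd$msd_um2 > 0
  if (sum(keep) < 3) {
    abort("Need at least 3 positive MSD values at lags <= `max_lag` to fit alpha.")
  }
  fit <- lm(log(msd_um2) ~ log(lag_s), data = msd[keep, ])
  s <- suppressWarnings(summary(fit))$coefficients
  new_diffusion_estimate(list(
    alpha = unname(coef(fit)[2]), se_alpha = s[2, 2],
    D_eff = NA_real_, se_D = NA_real_,
    intercept = NA_real_, se_intercept = NA_real_,
    fit_lag_max = max_lag, n_lags = sum(keep), n_points = NA_integer_
  ))
}

#' Effective diffusion coefficient from the short-lag MSD slope
#'
#' Fits an ordinary least-squares line through the first `n_points` MSD
#' values (at 3 Hz, lags 1/3, 2/3, 1 s) and returns
#' `D_eff = slope / 4` (2-D). The free intercept (default) absorbs static
#' localization offsets; `intercept = FALSE` forces the line through the
#' origin.
#'
#' @param msd an MSD tibble.
#' @param n_points number of leading lags to fit (default 3).
#' @param intercept fit a free intercept (default `TRUE`).
#' @return a `diffusion_estimate` with fields `D_eff`, `se_D`, `intercept`,
#'   `se_intercept`, `n_points`.
#' @export
estimate_deff <- function(msd, n_points = 3, intercept = TRUE) {
  msd <- dplyr::arrange(msd, .data$lag_s)
  if (nrow(msd) < n_points) {
    abort(sprintf("Need at least %d lags; MSD curve has %d.", n_points, nrow(msd)))
  }
  head_msd <- msd[seq_len(n_points), ]
  if (intercept) {
    fit <- lm(msd_um2 ~ lag_s, data = head_msd)
    s <- suppressWarnings(summary(fit))$coefficients
    slope <- unname(coef(fit)[2]); se_slope <- s[2, 2]
    icpt <- unname(coef(fit)[1]); se_icpt <- s[1, 2]
  } else {
    fit <- lm(msd_um2 ~ 0 + lag_s, data = head_msd)
    s <- suppressWarnings(summary(fit))$coefficients
    slope <- unname(coef(fit)[1]); se_slope <- s[1, 2]
    icpt <- 0; se_icpt <- 0
  }
  new_diffusion_estimate(list(
    alpha = NA_real_, se_alpha = NA_real_,
    D_eff = slope / 4, se_D = se_slope / 4,
    intercept = icpt, se_intercept = se_icpt,
    fit_lag_max = head_msd$lag_s[n_points], n_lags = NA_integer_,
    n_points = as.integer(n_points)
  ))
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' `d_p = k_B * T / (3 * pi * eta * D_eff)`, with the Boltzmann constant
#' `k_B = 1.380649e-23` N m / K, temperature in kelvin (default 296.15 K)
#' and medium viscosity in N m^-2 s (default 0.001, water-like buffer).
#'
#' @param D_eff effective diffusion coefficient, um^2/s; must be > 0.
#' @param T temperature, K.
#' @param eta dynamic viscosity, N m^-2 s.
#' @return hydrodynamic diameter in nm.
#' @export
stokes_einstein_diameter <- function(D_eff, T = 296.15, eta = 0.001) {
  if (any(!is.finite(D_eff)) || any(D_eff <= 0)) abort("`D_eff` must be > 0.")
  if (T <= 0 || eta <= 0) abort("`T` and `eta` must be positive.")
  d_m <- .kB * T / (3 * pi * eta * (D_eff * 1e-12))
  d_m * 1e9
}

#' Stokes-Einstein diffusion coefficient for a given diameter
#'
#' Algebraic inverse of [stokes_einstein_diameter()]:
#' `D = k_B * T / (3 * pi * eta * d_p)`.
#'
#' @param d_nm hydrodynamic diameter, nm; must be > 0.
#' @inheritParams stokes_einstein_diameter
#' @return diffusion coefficient in um^2/s.
#' @export
stokes_einstein_diffusion <- function(d_nm, T = 296.15, eta = 0.001) {
  if (any(!is.finite(d_nm)) || any(d_nm <= 0)) abort("`d_nm` must be > 0.")
  if (T <= 0 || eta <= 0) abort("`T` and `eta` must be positive.")
  D_m <- .kB * T / (3 * pi * eta * (d_nm * 1e-9))
  D_m * 1e12
}
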