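#' Synthetic single-particle trajectories and assay traces
#'
#' These generators produce every input the analysis pipeline consumes:
#' 2-D Brownian and fractional-Brownian (subdiffusive) bead trajectories
#' sampled at a fixed frame rate (default 3 Hz), fluorescence time courses
#' for translation / degradation reporters, and replicate rate-vs-concentration
#' profiles drawn from the biphasic crowding rate law. All randomness is
#' controlled by an explicit `seed` (base R Mersenne-Twister); a fixed seed
#' gives identical output across runs.
#'
#' @name synthetic-data
NULL

validate_sim_spec <- function(n_particles, n_frames, frame_interval,
                              localization_noise_sd) {
  if (n_particles < 1) abort("`n_particles` must be >= 1.")
  if (n_frames < 4) {
    abort("`n_frames` must be >= 4 so that at least lags 1..2 exist.")
  }
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be a positive number of seconds.")
  }
  if (localization_noise_sd < 0) abort("`localization_noise_sd` must be >= 0.")
  invisible(TRUE)
}

new_trajectory_tbl <- function(df, frame_interval) {
  out <- tibble::as_tibble(df)
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Frame interval of a trajectory table
#'
#' Returns the sampling interval (seconds) attached to a trajectory tibble
#' by the simulators or by [read_trajectories()].
#'
#' @param data a trajectory tibble.
#' @return the frame interval in seconds, or `NULL` if none is attached.
#' @export
frame_interval <- function(data) attr(data, "frame_interval", exact = TRUE)

#' Simulate 2-D Brownian bead trajectories
#'
#' Each axis takes independent Gaussian increments with variance
#' `2 * D * frame_interval`, so the two-dimensional ensemble MSD is
#' `4 * D * tau`. Optional localization noise (independent per frame) adds a
#' constant offset `4 * sd^2` to the MSD, which the effective-diffusion
#' estimator's free intercept absorbs.
#'
#' @param D diffusion coefficient, um^2/s; must be >= 0 (`D = 0` gives
#'   stationary particles).
#' @param n_particles number of trajectories.
#' @param n_frames frames per trajectory (>= 4).
#' @param frame_interval sampling interval in seconds (default 1/3 s, 3 Hz).
#' @param localization_noise_sd per-axis localization error, um (default 0).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a tibble with columns `particle_id`, `frame` (0-based), `x_um`,
#'   `y_um`, carrying the frame interval as an attribute (see
#'   [frame_interval()]).
#' @export
simulate_brownian_trajectories <- function(D,
                                           n_particles = 110,
                                           n_frames = 100,
                                           frame_interval = 1 / 3,
                                           localization_noise_sd = 0,
                                           seed = NULL) {
  if (!is.finite(D) || D < 0) abort("`D` must be a finite, non-negative diffusion coefficient.")
  validate_sim_spec(n_particles, n_frames, frame_interval, localization_noise_sd)
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * frame_interval)
  n_inc <- n_frames - 1
  build_axis <- function() {
    inc <- matrix(rnorm(n_particles * n_inc, sd = sd_step), nrow = n_inc)
    pos <- rbind(0, apply(inc, 2, cumsum))
    if (localization_noise_sd > 0) {
      pos <- pos + rnorm(length(pos), sd = localization_noise_sd)
    }
    pos
  }
  x <- build_axis()
  y <- build_axis()
  new_trajectory_tbl(
    tibble::tibble(
      particle_id = rep(seq_len(n_particles), each = n_frames),
      frame = rep(0:(n_frames - 1), times = n_particles),
      x_um = as.vector(x),
      y_um = as.vector(y)
    ),
    frame_interval
  )
}

# Autocovariance of unit-variance fractional Gaussian noise at integer lags.
fgn_autocovariance <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Draw `n_series` independent series of `n` unit-variance fGn increments with
# Hurst index H, by Davies-Harte circulant embedding (exact covariance).
# Falls back to Cholesky of the Toeplitz covariance when the embedding is
# not non-negative definite (can happen for short series at high H).
fgn_sample <- function(n, H, n_series) {
  r <- fgn_autocovariance(0:n, H)
  circ <- c(r, rev(r[2:n]))
  m <- length(circ) # 2n
  lambda <- Re(fft(circ))
  if (min(lambda) < -1e-8 * max(lambda)) {
    # Cholesky fallback: exact but O(n^3)
    cov <- toeplitz(r[1:n])
    L <- chol(cov)
    z <- matrix(rnorm(n * n_series), nrow = n)
    return(crossprod(L, z))
  }
  lambda <- pmax(lambda, 0)
  half <- m / 2
  # Hermitian-symmetric complex Gaussian spectrum per series
  w0 <- rnorm(n_series)
  whalf <- rnorm(n_series)
  u <- matrix(rnorm((half - 1) * n_series), nrow = half - 1)
  v <- matrix(rnorm((half - 1) * n_series), nrow = half - 1)
  W <- matrix(0 + 0i, nrow = m, ncol = n_series)
  W[1, ] <- w0
  W[half + 1, ] <- whalf
  W[2:half, ] <- (u + 1i * v) / sqrt(2)
  W[(half + 2):m, ] <- Conj(W[half:2, , drop = FALSE])
  sim <- mvfft(sqrt(lambda / m) * W)
  Re(sim[1:n, , drop = FALSE])
}

#' Simulate subdiffusive trajectories by fractional Brownian motion
#'
#' Each axis is fractional Brownian motion with Hurst index `alpha / 2`,
#' scaled so the two-dimensional ensemble MSD is
#' `4 * D_scale * tau^alpha`. Increments are exact fractional Gaussian noise
#' built by Davies-Harte circulant embedding (Cholesky fallback for short
#' series), so the increment autocovariance matches the closed form.
#' `alpha = 1` reduces to ordinary Brownian motion with `D = D_scale`;
#' `alpha = 2` gives ballistic (perfectly correlated) motion.
#'
#' @param D_scale generalized diffusion coefficient, um^2/s^alpha.
#' @param alpha MSD scaling exponent, in (0, 2].
#' @inheritParams simulate_brownian_trajectories
#' @return a trajectory tibble (see [simulate_brownian_trajectories()]).
#' @export
simulate_fbm_trajectories <- function(D_scale,
                                      alpha,
                                      n_particles = 110,
                                      n_frames = 100,
                                      frame_interval = 1 / 3,
                                      localization_noise_sd = 0,
                                      seed = NULL) {
  if (!is.finite(D_scale) || D_scale < 0) abort("`D_scale` must be finite and >= 0.")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2) {
    abort("`alpha` must lie in (0, 2].")
  }
  validate_sim_spec(n_particles, n_frames, frame_interval, localization_noise_sd)
  if (!is.null(seed)) set.seed(seed)
  n_inc <- n_frames - 1
  H <- alpha / 2
  # per-axis increment sd over one frame: MSD_x(dt) = 2 D dt^alpha
  sigma <- sqrt(2 * D_scale * frame_interval^alpha)
  build_axis <- function() {
    inc <- sigma * fgn_sample(n_inc, H, n_particles)
    pos <- rbind(0, apply(inc, 2, cumsum))
    if (localization_noise_sd > 0) {
      pos <- pos + rnorm(length(pos), sd = localization_noise_sd)
    }
    pos
  }
  x <- build_axis()
  y <- build_axis()
  new_trajectory_tbl(
    tibble::tibble(
      particle_id = rep(seq_len(n_particles), each = n_frames),
      frame = rep(0:(n_frames - 1), times = n_particles),
      x_um = as.vector(x),
      y_um = as.vector(y)
    ),
    frame_interval
  )
}

#' Simulate a dilution series of Brownian trajectories under Phillies's law
#'
#' Generates one Brownian trajectory set per relative cytoplasmic
#' concentration `phi`, with the diffusion coefficient following
#' `D(phi) = D0 * exp(-mu * phi)`. The exponential holds exactly in the
#' generator, so e.g. `mu = log(11)` makes `D(0) / D(1) = 11` exactly.
#'
#' @param D0 diffusion coefficient at `phi = 0` (filtrate), um^2/s; must be > 0.
#' @param mu Phillies scaling factor (dimensionless).
#' @param phi_list relative cytoplasmic concentrations to simulate.
#' @inheritParams simulate_brownian_trajectories
#' @return a trajectory tibble with an extra leading `phi` column.
#' @export
simulate_dilution_series_trajectories <- function(D0,
                                                  mu,
                                                  phi_list = seq(0.2, 2, by = 0.2),
                                                  n_particles = 110,
                                                  n_frames = 100,
                                                  frame_interval = 1 / 3,
                                                  localization_noise_sd = 0,
                                                  seed = NULL) {
  if (!is.finite(D0) || D0 <= 0) abort("`D0` must be a positive diffusion coefficient.")
  if (!is.finite(mu)) abort("`mu` must be finite.")
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(phi_list, function(phi) {
    set <- simulate_brownian_trajectories(
      D = D0 * exp(-mu * phi),
      n_particles = n_particles, n_frames = n_frames,
      frame_interval = frame_interval,
      localization_noise_sd = localization_noise_sd,
      seed = NULL
    )
    dplyr::mutate(set, phi = phi, .before = 1)
  })
  new_trajectory_tbl(dplyr::bind_rows(out), frame_interval)
}

#' Simulate a translation / degradation reporter time course
#'
#' Emulates plate-reader traces for the eGFP-translation and DQ-BSA
#' dequenching assays: a baseline lag, then a linear rise at `rate`,
#' optionally flattening into a plateau, plus Gaussian noise.
#'
#' @param rate linear-segment slope, AU/min.
#' @param lag_min lag before the linear segment starts, minutes.
#' @param t_grid sampling times, minutes (strictly increasing).
#' @param noise_sd Gaussian noise sd, AU.
#' @param baseline intensity before the lag ends, AU.
#' @param plateau_min time at which the trace flattens (default `Inf`, no
#'   plateau).
#' @param assay assay label, `"egfp"` or `"dqbsa"` (or `"s35"`).
#' @param phi relative cytoplasmic concentration label carried through.
#' @param seed integer seed.
#' @return a tibble with columns `time_min`, `intensity`, `assay`, `phi`.
#' @export
simulate_expression_timecourse <- function(rate,
                                           lag_min = 50,
                                           t_grid = seq(0, 150, by = 1),
                                           noise_sd = 0,
                                           baseline = 10,
                                           plateau_min = Inf,
                                           assay = c("egfp", "dqbsa", "s35"),
                                           phi = 1,
                                           seed = NULL) {
  assay <- match.arg(assay)
  if (is.unsorted(t_grid, strictly = TRUE)) abort("`t_grid` must be strictly increasing.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  t_eff <- pmin(pmax(t_grid - lag_min, 0), plateau_min - lag_min)
  intensity <- baseline + rate * t_eff
  if (noise_sd > 0) intensity <- intensity + rnorm(length(t_grid), sd = noise_sd)
  tibble::tibble(time_min = t_grid, intensity = intensity, assay = assay, phi = phi)
}

#' Simulate a securin-CFP degradation time course
#'
#' Emulates the plate-reader decay traces: after an optional brief initial
#' rise (a fluorophore-equilibration artifact spanning `rise_frames` points),
#' the normalized signal follows `A0 * exp(-k * t) + C`. The emitted
#' intensity is `background_level + amplitude * signal`, so the analysis
#' route (background subtraction, normalization by the maximum of the first
#' 15 points, constrained exponential fit) recovers `k`.
#'
#' @param A0 amplitude of the decaying component (fraction of the initial
#'   normalized signal).
#' @param k decay rate constant, 1/min.
#' @param C non-degradable floor (fraction).
#' @param rise_frames number of initial points replaced by a linear
#'   equilibration ramp (0 disables the artifact).
#' @param noise_sd Gaussian noise sd on the emitted intensity, AU.
#' @param t_grid sampling times, minutes; default 2 samples/min for 60 min.
#' @param amplitude emitted-intensity scale, AU.
#' @param background_level constant background added to the signal, AU.
#' @param phi relative cytoplasmic concentration label.
#' @param seed integer seed.
#' @return a tibble with columns `time_min`, `intensity`,
#'   `background_intensity`, `assay` (`"securin"`), `phi`.
#' @export
simulate_securin_timecourse <- function(A0 = 0.98,
                                        k = 0.1,
                                        C = 0.02,
                                        rise_frames = 0,
                                        noise_sd = 0,
                                        t_grid = seq(0, 60, by = 0.5),
                                        amplitude = 1000,
                                        background_level = 100,
                                        phi = 1,
                                        seed = NULL) {
  if (k < 0) abort("`k` must be >= 0.")
  if (is.unsorted(t_grid, strictly = TRUE)) abort("`t_grid` must be strictly increasing.")
  if (!is.null(seed)) set.seed(seed)
  signal <- A0 * exp(-k * t_grid) + C
  if (rise_frames > 0) {
    # equilibration ramp: the first points climb from 80% of the signal at
    # the end of the rise up toward it, so the trace increases before the
    # decay takes over (and the max of the early points is not point 1)
    ramp_idx <- seq_len(min(rise_frames, length(signal) - 1))
    anchor <- signal[length(ramp_idx) + 1]
    frac <- seq(0.8, 1, length.out = length(ramp_idx) + 1)[-(length(ramp_idx) + 1)]
    signal[ramp_idx] <- anchor * frac
  }
  intensity <- background_level + amplitude * signal
  if (noise_sd > 0) intensity <- intensity + rnorm(length(t_grid), sd = noise_sd)
  tibble::tibble(
    time_min = t_grid,
    intensity = intensity,
    background_intensity = background_level,
    assay = "securin",
    phi = phi
  )
}

#' Simulate replicate normalized rate-vs-concentration profiles
#'
#' Draws replicate reaction rates from the biphasic crowding rate law
#' `V(phi) = phi^2 * exp(-a * d_p * (phi - 1))` (normalized so the model
#' value at `phi = 1` is 1), with multiplicative Gaussian noise of
#' coefficient of variation `cv` (or additive noise of sd `cv`).
#'
#' @param d_p macromolecular diameter, nm.
#' @param a viscosity scaling factor, 1/nm (default 0.018).
#' @param phi_grid relative concentrations (default 0.2 to 2.0, step 0.2).
#' @param cv noise level: CV for multiplicative noise, sd for additive.
#' @param n_reps replicates per concentration.
#' @param noise `"multiplicative"` (default) or `"additive"`.
#' @param assay optional assay label carried through.
#' @param seed integer seed.
#' @return a tibble with columns `phi`, `rate`, `replicate`, `assay`.
#' @export
simulate_rate_profile <- function(d_p,
                                  a = 0.018,
                                  phi_grid = seq(0.2, 2, by = 0.2),
                                  cv = 0.10,
                                  n_reps = 6,
                                  noise = c("multiplicative", "additive"),
                                  assay = NA_character_,
                                  seed = NULL) {
  noise <- match.arg(noise)
  if (!is.finite(d_p) || d_p <= 0) abort("`d_p` must be a positive diameter in nm.")
  if (cv < 0) abort("`cv` must be >= 0.")
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(phi = phi_grid, replicate = seq_len(n_reps))
  truth <- eq2_rate(grid$phi, d_p = d_p, a = a)
  rate <- if (cv == 0) {
    truth
  } else if (noise == "multiplicative") {
    truth * (1 + rnorm(nrow(grid), sd = cv))
  } else {
    truth + rnorm(nrow(grid), sd = cv)
  }
  tibble::tibble(
    phi = grid$phi, rate = rate, replicate = grid$replicate, assay = assay
  )
}
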