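make_traj <- function(x, y = rep(0, length(x)), dt = 1) {
  tibble::tibble(particle_id = 1L, frame = seq_along(x) - 1L, x_um = x, y_um = y)
}

test_that("msd_trajectory matches the hand-evaluated worked example", {
  # x = [0, 1, 3, 6], N = 4: MSD(dt) = (1 + 4) / 2 = 2.5; MSD(2dt) = 9 / 1 = 9
  msd <- msd_trajectory(make_traj(c(0, 1, 3, 6)), frame_interval = 1)
  expect_equal(msd$msd_um2, c(2.5, 9))
  expect_equal(msd$weight, c(2, 1))
  expect_equal(msd$lag_s, c(1, 2))
})

test_that("stationary and uniform motion give the expected MSD curves", {
  expect_true(all(msd_trajectory(make_traj(rep(0, 8)), frame_interval = 1)$msd_um2 == 0))
  # x(i) = i: every displacement at lag n equals n, so MSD = n^2 (ballistic)
  msd <- msd_trajectory(make_traj(as.numeric(0:9)), frame_interval = 1)
  expect_equal(msd$msd_um2, (1:8)^2)
})

test_that("msd_trajectory agrees with a naive double-loop oracle", {
  set.seed(101)
  for (rep in 1:200) {
    N <- sample(3:12, 1)
    traj <- random_trajectory(N)
    got <- msd_trajectory(traj, frame_interval = 1 / 3)
    want <- msd_bruteforce(traj$x_um, traj$y_um, 1 / 3)
    expect_equal(got$msd_um2, want$msd_um2, tolerance = 1e-12)
    expect_equal(got$weight, want$weight)
  }
})

test_that("short trajectories are rejected", {
  expect_error(msd_trajectory(make_traj(c(0, 1)), frame_interval = 1), "short")
})

test_that("msd_ensemble is the weight-normalized mean of per-trajectory curves", {
  # traj 1: x=[0,1,3,6] (N=4, weight 2 at lag 1, MSD 2.5)
  # traj 2: N=5, constant step 1 -> MSD(dt)=1, weight 3
  t1 <- make_traj(c(0, 1, 3, 6))
  t2 <- make_traj(as.numeric(0:4))
  t2$particle_id <- 2L
  both <- dplyr::bind_rows(t1, t2)
  msd <- msd_ensemble(both, frame_interval = 1)
  expect_equal(msd$msd_um2[msd$lag_s == 1], (2 * 2.5 + 3 * 1) / 5) # 1.6
  expect_equal(msd$weight[msd$lag_s == 1], 5)
  # raw-sum audit mode
  raw <- msd_ensemble(both, frame_interval = 1, normalize = FALSE)
  expect_equal(raw$msd_um2[raw$lag_s == 1], 2 * 2.5 + 3 * 1)
  # single trajectory: ensemble == individual
  expect_equal(msd_ensemble(t1, frame_interval = 1)$msd_um2,
               msd_trajectory(t1, frame_interval = 1)$msd_um2)
  # identical copies: ensemble equals each individual curve
  copies <- dplyr::bind_rows(t1, dplyr::mutate(t1, particle_id = 2L),
                             dplyr::mutate(t1, particle_id = 3L))
  expect_equal(msd_ensemble(copies, frame_interval = 1)$msd_um2,
               msd_trajectory(t1, frame_interval = 1)$msd_um2)
})

test_that("ensemble MSD equals the pooled displacement average (oracle)", {
  set.seed(77)
  trajs <- dplyr::bind_rows(lapply(1:5, function(id) {
    tr <- random_trajectory(sample(4:10, 1), id = id)
    tr
  }))
  got <- msd_ensemble(trajs, frame_interval = 1)
  # oracle: pool all squared displacements with i <= N - n - 1 across particles
  for (lag in got$lag_s) {
    pooled <- c()
    for (id in unique(trajs$particle_id)) {
      tr <- trajs[trajs$particle_id == id, ]
      N <- nrow(tr); n <- lag
      if (N - n - 1 >= 1) {
        i <- seq_len(N - n - 1)
        pooled <- c(pooled, (tr$x_um[i + n] - tr$x_um[i])^2 +
                      (tr$y_um[i + n] - tr$y_um[i])^2)
      }
    }
    expect_equal(got$msd_um2[got$lag_s == lag], mean(pooled), tolerance = 1e-12)
  }
})

test_that("MSD is invariant under translation and rotation of coordinates", {
  set.seed(55)
  traj <- random_trajectory(20)
  base <- msd_trajectory(traj, frame_interval = 1)$msd_um2
  shifted <- dplyr::mutate(traj, x_um = x_um + 17, y_um = y_um - 3)
  expect_equal(msd_trajectory(shifted, frame_interval = 1)$msd_um2, base)
  th <- 0.83
  rotated <- dplyr::mutate(traj,
    x0 = x_um, x_um = cos(th) * x0 - sin(th) * y_um,
    y_um = sin(th) * x0 + cos(th) * y_um)
  expect_equal(msd_trajectory(rotated, frame_interval = 1)$msd_um2, base,
               tolerance = 1e-12)
})

test_that("conventional N - n terms mode differs as expected", {
  # x = [0,1,3,6]: conventional MSD(dt) = (1+4+9)/3, printed estimator (1+4)/2
  msd <- msd_trajectory(make_traj(c(0, 1, 3, 6)), frame_interval = 1,
                        conventional = TRUE)
  expect_equal(msd$msd_um2[1], (1 + 4 + 9) / 3)
  expect_equal(msd$lag_s, c(1, 2, 3))
})

test_that("fit_anomalous_exponent recovers exact power laws", {
  lags <- (1:6) / 3
  msd_lin <- tibble::tibble(lag_s = lags, msd_um2 = 4 * 0.36 * lags, weight = 1)
  expect_equal(fit_anomalous_exponent(msd_lin)$alpha, 1, tolerance = 1e-12)
  msd_sub <- tibble::tibble(lag_s = lags, msd_um2 = 1.2 * lags^0.88, weight = 1)
  expect_equal(fit_anomalous_exponent(msd_sub)$alpha, 0.88, tolerance = 1e-12)
  msd_bal <- tibble::tibble(lag_s = lags, msd_um2 = lags^2, weight = 1)
  expect_equal(fit_anomalous_exponent(msd_bal, max_lag = 2)$alpha, 2,
               tolerance = 1e-12)
  # only lags <= max_lag are used
  bent <- tibble::tibble(lag_s = c(lags, 2, 3), msd_um2 = c(lags, 50, 100),
                         weight = 1)
  expect_equal(fit_anomalous_exponent(bent, max_lag = 1)$alpha, 1,
               tolerance = 1e-12)
  expect_error(fit_anomalous_exponent(msd_lin[1:2, ]), "at least 3")
})

test_that("alpha recovery on fBm sets across exponents", {
  for (alpha in c(0.6, 0.88, 1.0)) {
    trajs <- simulate_fbm_trajectories(0.36, alpha, n_particles = 110,
                                       n_frames = 100, seed = 300 + alpha * 100)
    est <- fit_anomalous_exponent(msd_ensemble(trajs))
    expect_equal(est$alpha, alpha, tolerance = 0.08)
  }
})

test_that("estimate_deff fits the first three points with a free intercept", {
  lags <- (1:5) / 3
  msd <- tibble::tibble(lag_s = lags, msd_um2 = 1.44 * lags, weight = 1)
  est <- estimate_deff(msd)
  expect_equal(est$D_eff, 0.36, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  # static offset absorbed by the intercept, D unchanged
  msd_off <- tibble::tibble(lag_s = lags, msd_um2 = 1.44 * lags + 0.01, weight = 1)
  est_off <- estimate_deff(msd_off)
  expect_equal(est_off$D_eff, 0.36, tolerance = 1e-12)
  expect_equal(est_off$intercept, 0.01, tolerance = 1e-12)
  # through-origin mode differs on offset data
  est_origin <- estimate_deff(msd_off, intercept = FALSE)
  expect_gt(est_origin$D_eff, 0.36)
  # all-zero MSD -> D_eff 0
  msd0 <- tibble::tibble(lag_s = lags, msd_um2 = 0, weight = 1)
  expect_equal(estimate_deff(msd0)$D_eff, 0)
})

test_that("estimate_deff o msd_ensemble recovers the generating D", {
  # Brownian sets at the 1x diffusivity; 3-standard-error recovery across seeds
  ests <- vapply(1:8, function(s) {
    trajs <- simulate_brownian_trajectories(0.36, n_particles = 110,
                                            n_frames = 100, seed = s)
    estimate_deff(msd_ensemble(trajs))$D_eff
  }, numeric(1))
  expect_equal(mean(ests), 0.36, tolerance = 0.05)
  expect_true(all(abs(ests - 0.36) < 0.1))
})

test_that("Stokes-Einstein diameter matches the direct formula and inverts", {
  # k_B T / (3 pi eta D) with the stated constants: D = 4.338 um^2/s -> ~100 nm
  d <- stokes_einstein_diameter(4.338)
  expect_equal(d, 1.380649e-23 * 296.15 / (3 * pi * 0.001 * 4.338e-12) * 1e9,
               tolerance = 1e-12)
  expect_equal(d, 100, tolerance = 0.01)
  # round trip is the identity; halving D doubles d
  expect_equal(stokes_einstein_diameter(stokes_einstein_diffusion(57.3)), 57.3,
               tolerance = 1e-12)
  expect_equal(stokes_einstein_diameter(2) / stokes_einstein_diameter(4), 2,
               tolerance = 1e-12)
  expect_error(stokes_einstein_diameter(0), "> 0")
})
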