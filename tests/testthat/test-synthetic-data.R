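test_that("generators are deterministic under a fixed seed", {
  a <- simulate_brownian_trajectories(0.5, n_particles = 5, n_frames = 20, seed = 42)
  b <- simulate_brownian_trajectories(0.5, n_particles = 5, n_frames = 20, seed = 42)
  expect_identical(a, b)
  f1 <- simulate_fbm_trajectories(0.5, 0.8, n_particles = 4, n_frames = 16, seed = 7)
  f2 <- simulate_fbm_trajectories(0.5, 0.8, n_particles = 4, n_frames = 16, seed = 7)
  expect_identical(f1, f2)
  p1 <- simulate_rate_profile(104, seed = 3)
  p2 <- simulate_rate_profile(104, seed = 3)
  expect_identical(p1, p2)
})

test_that("zero diffusion gives stationary particles and all-zero MSD", {
  trajs <- simulate_brownian_trajectories(0, n_particles = 3, n_frames = 10, seed = 1)
  expect_true(all(trajs$x_um == 0) && all(trajs$y_um == 0))
  msd <- msd_ensemble(trajs)
  expect_true(all(msd$msd_um2 == 0))
})

test_that("Brownian increment variance matches 2 D dt to < 1% at large n", {
  D <- 1; dt <- 1 / 3
  trajs <- simulate_brownian_trajectories(D, n_particles = 1e4, n_frames = 50,
                                          frame_interval = dt, seed = 11)
  inc <- trajs |>
    dplyr::group_by(particle_id) |>
    dplyr::summarise(dx = list(diff(x_um)), dy = list(diff(y_um))) |>
    tidyr::unnest(c(dx, dy))
  v <- c(var(inc$dx), var(inc$dy))
  expect_equal(v, rep(2 * D * dt, 2), tolerance = 0.01)
})

test_that("Brownian increments pass a normality check at n = 1e5", {
  # Kolmogorov-Smirnov against the generating normal. A true-null p-value is
  # uniform, so any single draw can fall below a threshold; the check asks
  # that at least 4 of 5 independent sets clear p > 0.01.
  ps <- vapply(1:5, function(s) {
    trajs <- simulate_brownian_trajectories(0.36, n_particles = 1100,
                                            n_frames = 92, seed = s)
    inc <- unlist(tapply(trajs$x_um, trajs$particle_id, diff), use.names = FALSE)
    expect_gte(length(inc), 1e5)
    suppressWarnings(
      stats::ks.test(inc, "pnorm", sd = sqrt(2 * 0.36 / 3))$p.value
    )
  }, numeric(1))
  expect_gte(sum(ps > 0.01), 4)
})

test_that("fBm at alpha = 1 has uncorrelated increments like Brownian motion", {
  trajs <- simulate_fbm_trajectories(0.36, alpha = 1, n_particles = 200,
                                     n_frames = 100, seed = 8)
  ac <- trajs |>
    dplyr::group_by(particle_id) |>
    dplyr::summarise(r = stats::cor(diff(x_um)[-1], head(diff(x_um), -1)))
  # mean lag-1 autocorrelation ~ 0 within Monte-Carlo error
  expect_lt(abs(mean(ac$r)), 0.02)
})

test_that("fGn increment autocovariance matches the closed form", {
  alpha <- 0.7; H <- alpha / 2; D <- 1; dt <- 1
  trajs <- simulate_fbm_trajectories(D, alpha, n_particles = 2000, n_frames = 21,
                                     frame_interval = dt, seed = 13)
  inc <- matrix(unlist(tapply(trajs$x_um, trajs$particle_id, diff),
                       use.names = FALSE), nrow = 20)
  sigma2 <- 2 * D * dt^alpha
  for (k in 0:3) {
    emp <- mean(inc[1:(20 - k), ] * inc[(1 + k):20, ])
    theo <- sigma2 * 0.5 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
    expect_equal(emp, theo, tolerance = 0.05 * sigma2 + 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("fBm at alpha = 2 is ballistic (fitted exponent 2)", {
  trajs <- simulate_fbm_trajectories(0.5, alpha = 2, n_particles = 20,
                                     n_frames = 30, seed = 2)
  est <- fit_anomalous_exponent(msd_ensemble(trajs), max_lag = Inf)
  expect_equal(est$alpha, 2, tolerance = 1e-6)
})

test_that("fBm generator rejects exponents outside (0, 2]", {
  expect_error(simulate_fbm_trajectories(1, alpha = 0, seed = 1), "alpha")
  expect_error(simulate_fbm_trajectories(1, alpha = 2.5, seed = 1), "alpha")
  expect_error(simulate_brownian_trajectories(-1, seed = 1), "non-negative")
  expect_error(simulate_brownian_trajectories(1, n_frames = 3, seed = 1), "n_frames")
})

test_that("dilution series encodes Phillies's law exactly in the generator", {
  D0 <- 4; mu <- log(11)
  # exact generating coefficients: D0 e^{-mu phi}
  expect_equal(D0 * exp(-mu * c(0, 1, 2)), c(4, 4 / 11, 4 / 121))
  # mu = 0: same D at all phi -> same increment scale; check recovered D close
  trajs <- simulate_dilution_series_trajectories(
    D0 = 1, mu = 0, phi_list = c(0, 1), n_particles = 40, n_frames = 60, seed = 21
  )
  deff <- trajs |>
    msd_ensemble() |>
    dplyr::group_by(phi) |>
    dplyr::group_modify(~ tibble::tibble(D = estimate_deff(.x)$D_eff)) |>
    dplyr::ungroup()
  expect_equal(deff$D[1], deff$D[2], tolerance = 0.15)
})

test_that("expression time course is exactly lag + line when noise-free", {
  tc <- simulate_expression_timecourse(rate = 2, lag_min = 50,
                                       t_grid = seq(0, 150), noise_sd = 0)
  seg <- tc[tc$time_min >= 50 & tc$time_min <= 120, ]
  fit <- lm(intensity ~ time_min, data = seg)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-12)
  expect_true(all(tc$intensity[tc$time_min < 50] == tc$intensity[1]))
  # rate 0 -> flat trace, downstream estimate ~ 0 (cycloheximide analogue)
  flat <- simulate_expression_timecourse(rate = 0, noise_sd = 0)
  expect_warning(est <- linear_rate(flat, assay = "egfp"), "equal")
  expect_equal(est$slope_au_min, 0)
})

test_that("securin generator reproduces its target model in the noise-free limit", {
  tc <- simulate_securin_timecourse(A0 = 0.98, k = 0.1, C = 0.02,
                                    rise_frames = 0, noise_sd = 0)
  # normalized, background-corrected trace equals A0 e^{-kt} + C exactly
  norm <- (tc$intensity - tc$background_intensity) /
    max((tc$intensity - tc$background_intensity)[1:15])
  expect_equal(norm, (0.98 * exp(-0.1 * tc$time_min) + 0.02) / 1.00,
               tolerance = 1e-12)
  # rise artifact: max of first 15 points exceeds point 1
  tc_rise <- simulate_securin_timecourse(rise_frames = 5, noise_sd = 0)
  expect_gt(max(tc_rise$intensity[1:15]), tc_rise$intensity[1])
})

test_that("rate profile with cv = 0 equals the rate law exactly", {
  prof <- simulate_rate_profile(d_p = 104, cv = 0, n_reps = 2, seed = 1)
  expect_equal(prof$rate, eq2_rate(prof$phi, 104), tolerance = 1e-15)
  # model value at phi = 1 is 1 (normalized scale)
  expect_equal(unique(prof$rate[abs(prof$phi - 1) < 1e-9]), 1)
})
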