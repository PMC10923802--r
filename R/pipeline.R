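#' Run the full synthetic study end to end
#'
#' Generates a complete synthetic data set at known ground truth and runs
#' every analysis stage on it: (1) a Phillies dilution series of Brownian
#' bead trajectories, analysed by ensemble MSD, 3-point effective-diffusion
#' fits and a log-space Phillies regression; (2) subdiffusive fBm
#' trajectories at 1x analysed for the anomalous exponent; (3) replicate
#' rate-vs-concentration profiles for translation and degradation, refit
#' for the macromolecular diameters and concentration optima; (4) the
#' homeostasis model assembled from the two fitted diameters, with steady
#' states and a relaxation trajectory.
#'
#' @param seed integer seed controlling every stage.
#' @param D1 1x effective diffusion coefficient, um^2/s (default 0.36).
#' @param fold_change filtrate-to-1x diffusion fold change (default 11;
#'   `mu = log(fold_change)`).
#' @param alpha anomalous exponent for the subdiffusive set (default 0.88).
#' @param d_p_syn,d_p_deg generating diameters for the translation and
#'   degradation profiles, nm.
#' @param a viscosity scaling factor, 1/nm.
#' @param n_particles,n_frames trajectory set size.
#' @param cv rate-profile noise CV.
#' @param n_reps_syn,n_reps_deg replicates per concentration.
#' @return a list with elements `phillies` (fit), `deff_by_phi` (tibble),
#'   `alpha_fit` (`diffusion_estimate`), `fit_syn`, `fit_deg`
#'   (`rate_model_fit`s), `model` (`homeostasis_model`), `steady_states`
#'   (tibble), `relaxation` (tibble).
#' @export
run_synthetic_study <- function(seed = 1,
                                D1 = 0.36,
                                fold_change = 11,
                                alpha = 0.88,
                                d_p_syn = 104,
                                d_p_deg = 14,
                                a = 0.018,
                                n_particles = 110,
                                n_frames = 100,
                                cv = 0.10,
                                n_reps_syn = 6,
                                n_reps_deg = 4) {
  mu <- log(fold_change)
  D0 <- D1 * fold_change

  trajs <- simulate_dilution_series_trajectories(
    D0 = D0, mu = mu, phi_list = c(0, 0.5, 1, 1.5, 2),
    n_particles = n_particles, n_frames = n_frames, seed = seed
  )
  deff_by_phi <- trajs |>
    msd_ensemble() |>
    dplyr::group_by(.data$phi) |>
    dplyr::group_modify(function(msd, key) {
      est <- estimate_deff(msd)
      tibble::tibble(D_um2_s = est$D_eff, se = est$se_D)
    }) |>
    dplyr::ungroup()
  phillies <- fit_phillies(deff_by_phi)

  fbm <- simulate_fbm_trajectories(
    D_scale = D1, alpha = alpha, n_particles = n_particles,
    n_frames = n_frames, seed = seed + 1L
  )
  alpha_fit <- fit_anomalous_exponent(msd_ensemble(fbm))

  prof_syn <- simulate_rate_profile(
    d_p = d_p_syn, a = a, cv = cv, n_reps = n_reps_syn,
    assay = "translation", seed = seed + 2L
  )
  prof_deg <- simulate_rate_profile(
    d_p = d_p_deg, a = a, cv = cv, n_reps = n_reps_deg,
    assay = "degradation", seed = seed + 3L
  )
  fit_syn <- fit_dp(prof_syn, a = a)
  fit_deg <- fit_dp(prof_deg, a = a)

  model <- homeostasis_model(
    d_p_syn = fit_syn$d_p, d_p_deg = fit_deg$d_p, a = a
  )
  steady_states <- find_steady_states(model)
  relaxation <- simulate_relaxation(model, phi0 = 1.5, t_end = 400, dt = 0.1)

  list(
    phillies = phillies,
    deff_by_phi = deff_by_phi,
    alpha_fit = alpha_fit,
    fit_syn = fit_syn,
    fit_deg = fit_deg,
    model = model,
    steady_states = steady_states,
    relaxation = relaxation
  )
}
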