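# cytorate

Cytoplasm is crowded: in amphibian egg extract, macromolecules sit at about
60 mg/mL (relative concentration φ = 1; φ = 0 is protein-free filtrate,
φ = 2 a twice-concentrated retentate). Concentrating cytoplasm raises the
concentration of every enzyme and substrate — which should accelerate
bimolecular reactions — but also raises viscosity, which slows the diffusion
those reactions need. `cytorate` is an R package for analysing this
trade-off: it implements the single-particle-tracking and rate-extraction
estimators, the biphasic crowding rate model that links reaction optima to
the size of the machinery involved, and the feedback model in which the
offset between the synthesis and degradation optima makes φ = 1 a stable
homeostatic set point. It is aimed at quantitative cell biologists and
biophysicists working with extract dilution/concentration experiments, and
at anyone who wants a tested, synthetic-data-backed implementation of these
estimators.

The core quantitative pieces:

* **MSD estimation** from 2-D trajectories:
  MSDᵢ(nΔt) = (1/(N−n−1)) Σ [x(iΔt+nΔt)−x(iΔt)]² + [y(…)]², ensemble
  curves weighted by Nᵢ−n−1, effective diffusion D_eff = MSD/(4τ) from the
  first three lags, anomalous exponent α from log-log regression, and
  Stokes–Einstein diameters d_p = k_B T/(3πη D_eff).
* **Phillies's law** D(φ) = D₀ e^(−μφ) fitted in log space, and the linear
  size scaling μ = a·d_p (working value a = 0.018 nm⁻¹).
* **Rate extraction**: linear-segment slopes for eGFP / DQ-BSA / ³⁵S
  traces (fixed or auto-selected windows), constrained exponential fits
  A = A₀e^(−kt) + C for securin-CFP decay, within-batch 1× normalization,
  and the ×φ, ÷φ, ÷φ² assay-geometry transforms.
* **The crowding rate model** V(φ) = φ² e^(−a·d_p·(φ−1)), fitted for the
  single parameter d_p, with the closed-form optimum φ\* = 2/(a·d_p) and a
  Michaelis–Menten variant.
* **Homeostasis**: dφ/dt = γ(V_syn − V_deg), steady-state location and
  stability, RK4 relaxation simulation.
* **Synthetic data** for every input (Brownian and exact-fBm trajectories,
  reporter time courses, replicate rate profiles), so the whole pipeline is
  testable with known ground truth.

Functions take data frames first and return tibbles, so stages chain with
the pipe; fitted objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` views.

## Worked example

Simulate a bead-tracking dilution series in which diffusion falls 11-fold
per concentration unit, re-estimate D(φ) from the trajectories, and refit
Phillies's law:

```r
library(cytorate)
library(dplyr)

trajs <- simulate_dilution_series_trajectories(
  D0 = 0.36 * 11, mu = log(11), phi_list = c(0, 0.5, 1, 1.5, 2),
  n_particles = 110, n_frames = 100, seed = 1
)
deff <- trajs |>
  msd_ensemble() |>
  group_by(phi) |>
  group_modify(~ tibble::tibble(D_um2_s = estimate_deff(.x)$D_eff)) |>
  ungroup()
deff
#> # A tibble: 5 × 2
#>     phi D_um2_s
#>   <dbl>   <dbl>
#> 1   0    4.02
#> 2   0.5  1.20
#> 3   1    0.360
#> 4   1.5  0.106
#> 5   2    0.0329
fit_phillies(deff)
#> <phillies_fit>  D(phi) = D0 * exp(-mu * phi)
#>   D0 = 3.999 um^2/s (se 0.0445)
#>   mu = 2.408 (se 0.00909);  log-space R^2 = 1.0000;  n = 5
```

The recovered μ ≈ 2.41 ≈ ln 11 and D(1) ≈ 0.36 μm²/s: the 3-point MSD
estimator reproduces the generating Phillies curve from raw trajectories.

Refit the crowding rate model to a noisy synthetic translation profile and
read off the optimal concentration:

```r
prof <- simulate_rate_profile(d_p = 104, cv = 0.10, n_reps = 6, seed = 2)
fit <- fit_dp(prof)
tidy(fit)
#> # A tibble: 2 × 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 d_p       105.      1.80
#> 2 phi_opt     1.06    0.0182
```

A 104 nm machinery diameter puts the translation optimum essentially at
the physiological concentration (φ\* = 2/(0.018·104) = 1.07), while a
14 nm diameter puts the degradation optimum far above it (φ\* ≈ 7.9) —
and that asymmetry is what stabilizes the set point:

```r
m <- homeostasis_model(d_p_syn = 104, d_p_deg = 14)
find_steady_states(m)
#> # A tibble: 2 × 4
#>   phi_ss type     stability decay_rate
#>    <dbl> <chr>    <chr>          <dbl>
#> 1      0 boundary marginal      0
#> 2      1 interior stable       -0.0261
tail(simulate_relaxation(m, phi0 = 1.5, t_end = 400), 1)
#> # A tibble: 1 × 2
#>   time_h   phi
#>    <dbl> <dbl>
#> 1    400  1.00
```

The interior steady state sits at φ = 1 and is stable (local decay rate
−0.0261 h⁻¹ = γ × 0.018 × (14 − 104)); a concentration perturbed to 1.5×
relaxes back to 1× over a few hundred hours at the default turnover scale
γ = ln 2 / 43 h⁻¹.

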