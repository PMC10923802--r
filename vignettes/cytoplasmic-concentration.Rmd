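---
title: "How cytoplasmic concentration shapes diffusion and protein turnover: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How cytoplasmic concentration shapes diffusion and protein turnover: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytorate)
library(dplyr)
```

## The scientific question

Cytoplasm is a crowded medium: in amphibian egg extract, macromolecules sit
at roughly 60 mg/mL protein (we call this relative concentration
$\varphi = 1$, with $\varphi = 0$ the protein-free filtrate and
$\varphi = 2$ a twice-concentrated retentate). Concentrating the cytoplasm
raises the concentration of every enzyme and substrate — which should speed
up bimolecular reactions — but it also raises viscosity, which slows the
diffusion those reactions depend on. `cytorate` implements the quantitative
machinery to study this trade-off: single-particle-tracking estimators for
how diffusion changes with $\varphi$, rate extraction from reporter time
courses for how protein synthesis and degradation change with $\varphi$, a
biphasic rate model that ties the two together through the size of the
machinery involved, and the feedback model in which the difference between
the synthesis and degradation optima makes $\varphi = 1$ a stable set
point.

Because the underlying microscopy and plate-reader data are not deposited
in structured form, the package ships a first-class synthetic-data module:
every pipeline input can be generated with known ground truth, which is
also how the test suite validates each estimator.

## Diffusion: MSD estimators

For a 2-D trajectory with positions $x(i\Delta t), y(i\Delta t)$,
$i = 1..N$, the per-trajectory mean squared displacement at lag $n\Delta t$
is computed as

$$\mathrm{MSD}_i(n\Delta t) = \frac{1}{N-n-1} \sum_{i=1}^{N-n-1}
  \big[x(i\Delta t + n\Delta t) - x(i\Delta t)\big]^2 +
  \big[y(i\Delta t + n\Delta t) - y(i\Delta t)\big]^2 .$$

Note the $N-n-1$ terms: this drops the final overlapping displacement
relative to the conventional $N-n$-term estimator. We implement the
$N-n-1$ form as the default because it is the definition the analysis is
specified with, and provide `conventional = TRUE` for the usual estimator;
on long trajectories the difference is negligible, on short ones it is
visible (and the test suite pins both against a brute-force double loop).

The ensemble MSD weights each trajectory by its number of displacement
terms, $N_i - n - 1$. A raw weighted *sum* has the wrong units and grows
with the number of trajectories, so `msd_ensemble()` divides by the summed
weights — a weighted mean, equal to pooling all squared displacements
across particles (a property the tests verify directly). The unnormalized
sum remains available via `normalize = FALSE` for audit.

Two quantities are read off an MSD curve:

* `estimate_deff()` — an ordinary least-squares line through the first
  3 points (at 3 Hz: $\tau = 1/3, 2/3, 1$ s), with
  $D_\mathrm{eff} = \mathrm{slope}/4$. The line carries a free intercept by
  default: a static localization error of standard deviation $\sigma$ adds
  a constant $4\sigma^2$ to every MSD value, and a free intercept absorbs
  it without biasing the slope. Whether the original analysis used an
  intercept is not stated; the through-origin variant is exposed
  (`intercept = FALSE`) and the two agree exactly on offset-free data.
* `fit_anomalous_exponent()` — the slope of $\log \mathrm{MSD}$ vs
  $\log \tau$. The fit range is capped at 1 s by default, matching the
  time scale chosen for $D_\mathrm{eff}$; the cap is configurable since the
  range used for the published exponent is not stated.

`stokes_einstein_diameter()` converts $D_\mathrm{eff}$ measured in plain
buffer into a hydrodynamic diameter via
$d_p = k_B T / (3\pi\eta D_\mathrm{eff})$, with defaults $T = 296.15$ K and
$\eta = 10^{-3}$ N m$^{-2}$ s (water-like).

## Diffusion vs concentration: Phillies's law

Probe diffusion in macromolecule solutions follows
$D(\varphi) = D_0 e^{-\mu\varphi}$. `fit_phillies()` fits this in log
space — ordinary least squares of $\ln D$ on $\varphi$ — because the
exponential spans roughly two orders of magnitude across a 0–2×
dilution series and log-space residuals weight that range evenly; a
nonlinear fit in $D$-space would be dominated by the filtrate points.
Filtrate ($\varphi = 0$) measurements enter like any other point.

The scaling factor grows linearly with probe size, $\mu = a\,d_p$.
`fit_size_scaling()` fits this through the origin by default — the rate
model's derivation substitutes $\mu = a d_p$ with no offset — with a free
intercept available because the empirical relation is only approximately
linear. The working value used throughout is $a = 0.018$ nm$^{-1}$.

## Rates from fluorescence time courses

Translation (eGFP synthesis, $^{35}$S incorporation) and degradation
(DQ-BSA dequenching) rates are slopes of the linear segment of an
intensity–time trace (`linear_rate()`). Default windows are 50–120 min
(eGFP), 25–120 min (DQ-BSA) and start–75 min ($^{35}$S). The original
segments were curated by hand; as a deterministic replacement,
`window = "auto"` slides windows of length $\ge 30$ min in 5-min steps and
keeps the window with maximal $R^2$, breaking ties by longest window then
earliest start. On a lag-then-line trace this provably selects the linear
part and returns the exact slope.

Securin-CFP degradation is fitted by `securin_decay_rate()`:
background-subtract, divide by the maximum of the first 15 points
(7.5 min at 2 samples/min), then a bounded Levenberg–Marquardt fit of
$A = A_0 e^{-kt} + C$ with $A_0 \in (0.95, 1.2]$, $C \in [0, 0.05]$,
$k \in [0, 10]$ min$^{-1}$. The upper bounds on $A_0$ and $k$ are loose
physical limits added for optimizer stability (the stated constraints give
only the lower/interval bounds). Two numerical choices matter:

* The fit starts at the early maximum (the same point that defines the
  normalization), with time re-zeroed there. Early points can rise while
  the fluorophore equilibrates; including them biases $k$ low by roughly
  10% on synthetic traces with a 5-point rise, whereas starting at the
  maximum restores exact recovery in the noise-free limit.
* Parameters landing on a bound are flagged, and a trace that pins both
  $A_0$ and $C$ (e.g. a constant trace, for which $A_0 + C$ is a
  non-identifiable ridge at $k = 0$) triggers an explicit warning.

`normalize_rates()` divides rates by the mean rate measured at
$\varphi = 1$ within the same egg batch (batch column optional), and
`transform_rate()` applies the $\varphi$-power corrections that convert
between assay geometries: $\times\varphi$ when the substrate is co-diluted
with the machinery, $\div\varphi$ for the apparent bimolecular rate
constant, $\div\varphi^2$ for the double correction used with metabolic
labeling.

## The biphasic rate model

With enzyme and substrate both proportional to $\varphi$ and a
diffusion-limited association constant scaling as
$e^{-a d_p(\varphi - 1)}$, the velocity relative to its 1× value is

$$V(\varphi) = \varphi^2\, e^{-a d_p (\varphi - 1)},$$

which rises as $\varphi^2$ at low concentration and is eventually crushed
by viscosity. Its maximum has the closed form
$\varphi^\ast = 2/(a\,d_p)$, so the size of the machinery sets the optimal
concentration: $d_p = 104$ nm gives $\varphi^\ast = 1.07$, $d_p = 14$ nm
gives $\varphi^\ast = 7.94$.

`fit_dp()` fits $d_p$ by nonlinear least squares with $a$ fixed (the model
then has a single adjustable parameter) and the amplitude fixed at 1,
because the data are normalized to the 1× rate; a free amplitude and
per-point weights are available as options. The starting value is derived
from the grid argmax of the mean profile ($d_p^{(0)} = 2/(a
\varphi_\mathrm{peak})$), making the fit self-starting. The standard error
of $\varphi^\ast$ uses first-order (delta-method) propagation,
$\mathrm{se}(\varphi^\ast) = \varphi^\ast\,\mathrm{se}(d_p)/d_p$; this is
the documented method, and it will not exactly reproduce a standard error
computed from unrounded fit internals elsewhere.

`mm_rate()` is a Michaelis–Menten extension with two extra dials: the
saturation $s = S/K_M$ at 1×, and the fraction $f$ of binding resistance
that is diffusion-limited at 1× (the diffusion-limited part of $K_M$
scales inversely with the Phillies factor). It reduces exactly to the
mass-action law as $s \to 0$, $f = 1$, and becomes independent of
$a d_p$ at $f = 0$. Its published algebraic form is in supplementary
material not reproduced here, so this is a documented reconstruction with
the stated limiting behaviour, not a transcription.

## Homeostasis

The verbal stability argument is made quantitative with the minimal mass
balance

$$\frac{d\varphi}{dt} = \gamma\,\big[V_\mathrm{syn}(\varphi) -
  V_\mathrm{deg}(\varphi)\big],$$

with both laws normalized to 1 at $\varphi = 1$ (so the net flux vanishes
there by construction) and $\gamma$ a single turnover time scale, default
$\ln 2 / 43\ \mathrm{h^{-1}}$ from the cited 43 h median protein
half-life — a conjectured scale, exposed as a parameter. Near the set
point the linearized decay rate is $\gamma\,a\,(d_{p,\mathrm{deg}} -
d_{p,\mathrm{syn}})$; with the fitted diameters the dimensionless slope is
$0.018 \times (14 - 104) = -1.62$, negative, hence stable whenever the
synthesis machinery is larger than the degradation machinery.

`find_steady_states()` scans the net flux for sign changes and polishes
roots with bisection; $\varphi = 0$ is reported separately as a degenerate
boundary equilibrium (both laws vanish there). `simulate_relaxation()`
integrates with a fixed-step classical Runge–Kutta (RK4) scheme —
deterministic and reproducible for a smooth 1-D system — with the step
checked against the local decay rate and divergence detected at run time;
the test suite cross-checks it against an adaptive-step reference
integrator (`deSolve::ode`, lsoda) to $10^{-7}$.

## The synthetic-data module

The generators emulate the statistical structure the estimators assume,
at the study's own conditions:

* **Brownian trajectories** — per-axis Gaussian increments of variance
  $2D\Delta t$, default 3 Hz sampling, 110 particles × 100 frames (the
  size of the published tracking ensemble). Optional localization noise
  (default 0) creates the MSD intercepts that motivate the free-intercept
  estimator.
* **Subdiffusive trajectories** — exact fractional Brownian motion per
  axis (Hurst $H = \alpha/2$), synthesized by Davies–Harte circulant
  embedding of fractional Gaussian noise with a Cholesky fallback for
  short series; exactness over approximate recursive schemes is the point,
  since the generator doubles as the reference for the exponent estimator.
  Scaled so the ensemble MSD is $4 D \tau^\alpha$.
* **Dilution series** — Brownian sets with $D(\varphi) = D_0
  e^{-\mu\varphi}$ holding exactly in the generator.
* **Expression traces** — baseline, lag, linear rise (optional plateau),
  Gaussian noise. The published traces are shown but not parameterized, so
  all shape parameters are exposed.
* **Securin traces** — $A_0 e^{-kt} + C$ at 2 samples/min with an optional
  equilibration ramp over the first few points and a constant background
  channel.
* **Rate profiles** — the biphasic law on the $\varphi = 0.2..2.0$
  (step 0.2) grid spanning the experimental dilution range, with
  multiplicative noise of CV 0.10 by default (the measurement noise level
  is not published; 10% is a realistic plate-reader replicate scatter and
  is the level used throughout the tests), 6 replicates per concentration
  for translation-like profiles and 4 for degradation-like ones, matching
  the experimental replicate counts.

What the generators deliberately do **not** emulate: spatial heterogeneity
of the cytoplasm (the published position-to-position variability in bead
mobility), detection/linking failures and gapped trajectories, bleaching
and flat-field artifacts, and vendor file formats. Passing tests therefore
demonstrate estimator correctness under the stated statistical model, not
robustness to those real-data complications — upstream image processing is
assumed done.

## Problem sizes and numerical tolerances

The test suite and the acceptance script regenerate everything they check.
Trajectory checks use 110 particles × 100 frames per set (the published
ensemble size), averaged over 8–10 seeds where a mean is asserted;
increment-level distribution checks use $10^4$–$10^5$ increments. Rate
profile refits pool 25–50 seeds for bias/coverage properties. Root
finding uses a 2000-point scan with $10^{-10}$ bisection tolerance; the
RK4 default step is 0.1 h against a linearized decay time of ~38 h.
Degenerate inputs (zero diffusion, flat traces, all-zero MSD,
non-identifiable constant securin traces) are part of the tested surface,
and ties in the auto-window search are broken deterministically (longest
window, then earliest start).

## Known limitations

* The $N-n-1$ estimator convention and the weighted-mean reading of the
  ensemble formula are documented choices where the printed definitions
  are unconventional or incomplete; both alternatives are exposed.
* The degradation-profile refit (4 replicates, shallow optimum near the
  grid edge) has ~14% seed-to-seed coefficient of variation in single
  draws; averages across draws are stable and that is how the package's
  own reproduction script reports it.
* `mm_rate()` is a reconstruction (see above), suitable for exploring
  saturation and reaction-control effects, not for quoting against the
  supplementary expression.
* The homeostasis model is a 1-D deterministic mass balance; it contains
  no synthesis burden, dilution by growth, or stochasticity, and $\gamma$
  only sets the clock, not the steady state.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates all inputs
and writes the recomputed quantities (concentration optima, refitted
diameters, recovered exponent and diffusion contrast, and the settled
steady state) as JSON; see the README for how to run it.
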