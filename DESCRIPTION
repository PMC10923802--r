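Package: cytorate
Title: Cytoplasmic Concentration, Diffusion, and Protein Turnover Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the macromolecule concentration of
    cytoplasm controls diffusion and protein turnover. Implements mean
    squared displacement (MSD) estimation from single-particle
    trajectories, anomalous-exponent and effective-diffusion fits,
    Stokes-Einstein size estimation, Phillies's-law scaling of diffusion
    with relative cytoplasmic concentration, extraction of translation and
    degradation rates from fluorescence time courses, nonlinear fitting of
    a biphasic crowding rate model V = phi^2 exp(-a d_p (phi - 1)), a
    Michaelis-Menten variant, and simulation of the resulting
    concentration-homeostasis feedback. A synthetic-data module generates
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
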