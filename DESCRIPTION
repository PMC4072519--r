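Package: cfep
Title: Optimal Reaction Coordinates and Cut-Based Free-Energy Profiles for
    Longitudinal Metabolomic Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Learns a scalar reaction coordinate (a dynamical biomarker) from
    short multivariate longitudinal trajectories, such as binned NMR
    metabolomic spectra sampled daily around an intervention. The coordinate
    is a linear combination of log-transformed spectral bin intensities,
    optimized either against terminal clinical outcomes (a committor-like,
    boundary-constrained least-squares fit) or without labels as the slowest
    relaxation mode of the observed dynamics (a generalized eigenvalue
    problem). Cut-based free-energy profiles, coordinate-dependent diffusion
    coefficients, equilibrium landscape reconstruction from non-equilibrium
    trajectory ensembles, and model-based plus empirical outcome
    probabilities (splitting probabilities with Agresti-Coull intervals)
    describe the projected dynamics as diffusion on a free-energy landscape.
    Includes a synthetic-cohort simulator with exact finite-state oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
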