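Package: woundsim
Title: Stochastic Continuum Simulation and Migration Statistics for
    Collective Keratinocyte Wound Closure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates collective keratinocyte migration during wound
    closure with a stochastic diffusion-advection continuum model on the
    unit square: nonlinear volume-filling diffusion limited by cell-cell
    adhesion, anisotropic coordinated directionality, and randomly
    localized wound-edge retraction events treated as advection. Includes
    an explicit finite-difference solver with a second-order WENO
    advection scheme, wound observables (area, edge length, closure
    proportion), parameter sweeps and condition calibration, and a
    companion migration-statistics suite for cell trajectories and PIV
    velocity fields (mean squared displacement, velocity autocorrelation,
    von Mises direction fitting, angular deviation, spatial
    autocorrelation and correlation length constants), together with
    seeded synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
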