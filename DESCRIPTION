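Package: cavitr
Title: Cavitation Bubble Dynamics and Particle-Trajectory Analysis for Water
    and Soft Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum models of cavitation bubble growth, pulsation and
    collapse (equilibrium threshold pressure, damped volume pulsation,
    Rayleigh-Plesset integration, classical nucleation-time scaling) together
    with estimators that post-process molecular-dynamics-style particle
    trajectories: void/cavity detection on a periodic occupancy grid,
    isosurface reconstruction and sphericity, virial global pressure from
    per-atom stress, density excluding cavity volume, threshold-pressure
    extraction, mean-square displacement and diffusion coefficients, and
    Green-Kubo shear viscosity. Includes deterministic synthetic-trajectory
    generators with recorded ground truth so every estimator can be validated
    without running molecular dynamics, and readers/writers for LAMMPS text
    dumps, extended XYZ and unit-annotated CSV series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
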