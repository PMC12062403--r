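Package: finprop
Title: Self-Propelled Balistiform Swimmer Simulation and Hydrodynamic
    Performance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how median-fin (balistiform) swimmers such
    as the filefish Rudarius ercodes trade propulsive efficiency for
    acceleration when they fold their caudal fin. Provides a parametric
    swimmer geometry with a configurable caudal-fin opening angle,
    traveling-wave fin kinematics with a startup ramp and length-preserving
    fin-ray deformation, a two-dimensional incompressible Navier-Stokes
    solver with a direct-forcing immersed moving boundary, a second-order
    backward-difference self-propulsion update with x-only freedom, the
    hydrodynamic performance statistics used in fish-swimming energetics
    (average acceleration, Reynolds number, Froude efficiency, cost of
    transport, drag coefficient, thrust-drag decomposition), a velocimetry
    module for markerless pose-estimation keypoint tracks, and synthetic
    data generators with closed-form ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
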