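Package: cellflow
Title: Coarse-Grained Viscoelastic Cell Models in Dissipative Particle Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for coarse-grained viscoelastic eukaryotic cells in flow.
    Cell and nucleus membranes are closed triangulated surfaces carrying
    worm-like-chain in-plane elasticity, bending resistance, global area and
    volume constraints, and pairwise membrane viscosity with the matching
    thermal noise; the cytoskeleton and nucleus interior are networks of
    Kelvin-Voigt (spring plus damper in parallel) bonds.  The surrounding
    fluid is modeled with dissipative particle dynamics (DPD).  The package
    provides virtual micropipette-aspiration and obstacle-channel
    experiments, Theret-model estimators of whole-cell elastic and viscous
    moduli, mesh generation and audit tools, and LAMMPS/VTK/XYZ exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
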