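Package: duplexflip
Title: Helical Parameters, Base-Flipping Coordinates and Free-Energy
    Profiles for DNA Duplex Trajectories
Version: 0.1.0
Authors@R:
    person("Maintainer", "Duplexflip", email = "maintainer@duplexflip.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for frame ensembles of B-DNA duplexes:
    builds idealized B-form duplexes from the twelve rigid-body helical
    parameters (an exactly invertible forward model), generates seeded
    synthetic trajectory ensembles with Gaussian parameter fluctuations and
    a two-state (closed/open) switching process emulating wobble-pair
    dynamics, and measures base-pair and base-step parameters, lambda
    angles, a pseudo-dihedral base-flip coordinate, hydrogen-bond
    occupancies, solvent-accessible surface areas, histogram potentials of
    mean force with per-run averaging and 99 percent confidence intervals,
    and an adaptive-biasing-force estimator on a reduced one-dimensional
    Langevin model of the flip coordinate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
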