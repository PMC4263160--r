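Package: elltube
Title: Field-Directed Self-Assembly of Polarized Colloidal Ellipsoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulation of hard parallel prolate spheroids
    whose field-induced polarization is represented by a pair of opposite
    point charges on the long axis. Provides Metropolis Monte Carlo in a
    periodic box with Ewald summation, an ideal-dipole control mode,
    morphology classification of particle configurations (fluid, string,
    compact aggregate, sheet, hollow tube) with periodic-boundary spanning
    analysis, and constrained minimum-energy calculations for idealized
    sheet and tube aggregates that rationalize why finite sheets close
    into tubes. All quantities are in reduced units: lengths in units of
    the short semi-axis R, energies in units of kT, with a single
    dimensionless electrostatic coupling parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
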