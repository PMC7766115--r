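Package: polyeject
Title: Two-Stage Scaling Theory and Langevin Dynamics of Polymer Ejection
    from a Spherical Cavity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the ejection of a flexible polymer from a
    spherical cavity through a nanopore into a semi-space. Implements the
    two-stage (confined/non-confined) blob scaling theory for the ejection
    velocity and ejection time, the osmotic-pressure criterion and Kramers
    nucleation time for the pre-ejection stall, a coarse-grained bead-spring
    Langevin-dynamics simulator of the pumping/equilibration/ejection
    protocol in reduced Lennard-Jones units, and an analysis pipeline that
    turns ensembles of ejection traces into waiting-time functions, velocity
    profiles, nucleation times, trimmed m(t) fits and power-law exponents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
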