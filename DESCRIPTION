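Package: cascadeclock
Title: Timing Precision of Stochastic Gene-Activation Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models sequential gene-activation cascades as burst-dilution
    hybrid stochastic processes (piecewise-deterministic Markov processes)
    and quantifies the precision of the molecular timer they implement.
    Provides an exact event-driven simulator of first-passage times to
    activation thresholds, closed-form transient moments of gene products,
    small-noise analytic approximations for the mean and noise of the
    first-passage time for cascades of arbitrary length, and a constrained
    optimizer that places activation thresholds to minimize timing noise at
    a fixed mean first-passage time, including the criterion deciding when
    adding a gene to a cascade improves timekeeping.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
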