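Package: perfusim
Title: Simulation of Eye Perfusion Techniques for Outflow Facility Measurement
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter viscoelastic model of the eye and its
    perfusion system for simulating outflow facility experiments.
    Implements constant-flow, gravity-driven constant-pressure, and
    pump-driven constant-pressure perfusion controllers, physiologically
    realistic intraocular pressure noise generators (enucleated eye,
    anesthetized and conscious animal regimes), steady-state detection by
    window, ratio, and recursive exponential-regression criteria, and a
    facility-experiment driver that estimates outflow facility by
    pressure-flow regression. Traces, detection results, and experiment
    summaries are returned as tidy tibbles with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
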