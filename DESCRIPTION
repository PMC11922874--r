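Package: succdyn
Title: Process-Based Dynamic Model of Succinic Acid Batch Fermentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Kinetic simulation of anaerobic batch fermentation of glucose by
    Actinobacillus succinogenes, in which microbial growth and the production
    of succinic, acetic and formic acids are regulated by the cellular ATP/ADP
    balance. Process rates follow Michaelis-Menten kinetics gated by logistic
    response curves; the coupled ODE system is integrated with a stiff solver.
    Includes least-squares calibration of the kinetic parameters by
    Nelder-Mead simplex, local one-at-a-time (elemental-effect) sensitivity
    analysis, an initial-glucose sweep experiment for yield optimisation, and
    a synthetic-data generator that emulates batch sampling with measurement
    noise so that calibration workflows can be exercised without the original
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
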