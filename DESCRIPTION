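Package: sulfkin
Title: Plug-Flow Kinetics and Electron-Donor Mass Balance for Sulfate-Reducing Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing steady-state performance of up-flow anaerobic
    packed-bed sulfate-reducing bioreactors operated over a hydraulic retention
    time ladder. Computes zone-wise sulfate conversions and volumetric sulfate
    reduction/loading rates, fits first-order and nth-order rate laws along an
    ideal plug-flow reactor by multi-start nonlinear least squares with t-based
    95% confidence bands, and attributes observed sulfate reduction to lactate,
    propionate and acetate oxidation through a stoichiometric ledger that
    predicts zone-wise acetate concentrations. Includes a seeded synthetic
    steady-state data generator so every pipeline stage is testable without
    reactor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
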