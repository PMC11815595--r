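Package: violakin
Title: Dual-Substrate Growth Kinetics and Fed-Batch Design for Plant Cell
    Suspension Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of sucrose- and nitrate-limited growth of
    plant cell suspension cultures (developed around Viola odorata batch and
    fed-batch bioreactor cultivations). Implements Monod, Sigmoid and combined
    Monod-Sigmoid dual-substrate growth kernels with Luong substrate
    inhibition, fixed-step fourth-order Runge-Kutta simulation of batch and
    fed-batch trajectories with dilution terms, weighted least-squares
    parameter estimation under box bounds via a Rosenbrock rotating-directions
    optimizer with seeded Latin-hypercube multi-start, F-test model
    discrimination (variance-ratio and nested-SSE), local finite-difference
    parameter sensitivity ranking, exhaustive in-silico enumeration and
    ranking of fed-batch feed strategies, and a synthetic time-course
    generator with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
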