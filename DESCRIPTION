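Package: n1sim
Title: Simulation and Design of N-of-1 (Single-Patient Crossover) Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic time-series simulation of N-of-1 (multiple-crossover,
    single-patient) comparative effectiveness studies. Treatment effects
    follow exponential wash-in/wash-out dynamics, the patient's baseline
    drifts as a Wiener process, the true outcome state relaxes toward the
    baseline-plus-treatment target with additive process noise, and
    observations add instrument noise with optional transformations to
    discrete outcome types (scores, counts, proportions, binary). Includes
    the AHRQ-style fixed-effects regression and a median-differencing
    decision rule for analyzing observed data, and a replicated-simulation
    harness for estimating statistical power, effect-estimate accuracy, and
    design recommendations (treatment ordering, sampling frequency, period
    length, block count).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
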