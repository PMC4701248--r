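Package: mcpsim
Title: Model-Based Simulation and Early Validation of Medical Cyber-Physical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulation framework for closed-loop medical
    cyber-physical systems built around a diabetic patient model.
    Provides generalized-linear-model (GLM) generators for ICU vital signs
    with inverse-Gaussian and Gamma canonical links, Bergman minimal-model
    glucose-insulin kinetics (nonlinear and linearized, with operating-point
    computation and state-space linearization), PID glucose control, periodic
    sensor and insulin-pump device models with a timed state machine,
    runtime monitoring of pump safety properties, structural coverage
    reporting (decision, condition, MC/DC), and a synthetic patient-cohort
    generator with in-package IRLS fitting of the vital-sign GLMs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
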