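Package: tcelltol
Title: Inertial-Elastic Dynamics of T-Cell Tolerance and Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates an inertial/elastic second-order ordinary
    differential equation model of effector T-cell dynamics coupled to an
    exponentially growing pathogen population. Integration is event-driven:
    runs terminate either when the pathogen falls below its infectivity
    threshold (elimination) or when the effector population returns to
    baseline with residual pathogen (tolerance by early contraction).
    Includes a multi-clone extension for immunodominance and compensatory
    expansion experiments, non-dimensionalization utilities, phase-diagram
    sweeps over the reduced parameter plane, bisection search for the
    critical pathogen growth rate, a fixed-step Runge-Kutta reference
    integrator for validation, a preset registry of qualitative regimes,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
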