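Package: dabicoag
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of Intravenous
    Dabigatran Anticoagulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated pharmacokinetic-pharmacodynamic analysis of
    intravenous dabigatran and its anticoagulant effect on whole-blood
    coagulation readouts (activated clotting time and thromboelastometric
    reaction time). Implements a two-compartment disposition model with
    allometric size standardization, delayed-effect models (effect
    compartment and turnover) driving a sigmoid Emax concentration-response,
    nonlinear mixed-effects estimation by the Laplace approximation with
    combined residual error and log-normal between-subject variability,
    sequential PK-then-PD fitting, objective-function model comparison, and
    prediction-corrected visual predictive checks. Includes a seeded
    synthetic-cohort simulator reproducing a single-dose rabbit study design
    for simulation-estimation (parameter recovery) studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    deSolve,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
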