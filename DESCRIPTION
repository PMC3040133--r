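Package: rnaikin
Title: Kinetic Models of siRNA-Mediated mRNA Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling dose-response curves of RNA interference in
    mammalian cells. Implements four kinetic laws for siRNA-induced mRNA
    degradation (mass-action, cooperative mass-action, enzymatic
    Michaelis-Menten, and phenomenological Hill), their closed-form
    steady-state knockdown ratios, time-course integration of the underlying
    ODE system, standard-error-weighted global parameter fitting with a
    differential-evolution search, leave-one-out cross-validated prediction
    error for model comparison, and a seeded synthetic dose-response
    generator emulating triplicate qPCR/FACS knockdown measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
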