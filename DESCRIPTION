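Package: swimchain
Title: Chain-Link Resistive Models of Undulatory Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forced damped oscillation toolkit for undulatory swimming.
    Models a slender swimmer as a planar chain of rigid links joined by stiff
    penalty springs, driven by a preferred-curvature muscle moment and damped
    by resistive hydrodynamic drag (Taylor drag at intermediate-to-high
    Reynolds number, Lighthill slender-body drag at low Reynolds number).
    Provides the nonlinear equations of motion, the leading-order (small
    inclination) equations with their closed-form steady-velocity estimator,
    a constraint-elimination oracle for validation, passive-swimming scenarios
    under external forcing or flow, eigenmode analysis of the linearized
    spring-inertia-damper system, Euler-Bernoulli beam-mode decomposition of
    simulated kinematics, cycle-averaged power-transfer accounting, and
    optimization of a five-parameter gait-curvature family for fast swimming.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
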