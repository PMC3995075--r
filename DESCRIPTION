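Package: gravibend
Title: Graviproprioceptive Models of Shoot Gravitropism in Growing Organs
Version: 0.1.0
Authors@R: person("gravibend", "maintainers", email = "gravibend@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of shoot gravitropism under the combined
    control of graviception (sensing of inclination) and proprioception
    (sensing of curvature). Implements the classical non-elongating
    graviproprioceptive model and its growth-explicit extension in which
    differential growth is the motor of curvature change, on a Lagrangian
    grid of material elements advected by elongation. Provides closed-form
    steady states (exponential-decay and real-order Bessel profiles), the
    model-discrimination statistic and its critical proprioceptive gain,
    regime diagnostics for passive orientation drift and curvature fixation,
    kinematic phenotyping of the bending number from digitized organ
    midlines, a synthetic-midline fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
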