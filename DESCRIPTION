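Package: tonegap
Title: Firing-Rate Dynamics of the Auditory Continuity Illusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Idealized firing-rate model of a neural population driven by
    tones and noise, built to study the auditory continuity illusion.
    Provides the sigmoid recurrent-excitation population equation with
    sustained, transient (onset/offset) and mutual-inhibition input
    pathways; builders for tone-only, masking and continuity stimulus
    scenarios; closed-form equilibrium curves with their saddle-node
    knees and a region classification of parameter space; knee-placement
    calibration of model variants; linear and numerically integrated
    separatrix approximations to basin boundaries in the rate-transient
    phase plane; event-driven simulation of responses; and analytic and
    simulation-based masking and continuity threshold curves, including
    parameter sweeps. A small command-line interface reproduces the
    data behind the standard diagnostic figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
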