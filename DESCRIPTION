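Package: syncopeBIA
Title: Budget Impact of Early Implantable Loop Recorder Diagnosis in
    Unexplained Syncope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time Markov cohort model comparing early implantable
    loop recorder (ILR) diagnosis against a conventional diagnostic pathway
    (CDP) for recurrent unexplained syncope, from the perspective of a
    national payer. Implements the three-state quarterly cohort recursion
    (undiagnosed, diagnosed, dead) with life-table mortality adjusted by a
    hazard ratio, per-event diagnostic yields, a component cost model with
    annual discounting, scenario-based diagnostic workup costing, one-way
    (tornado) and threshold sensitivity analysis, probabilistic sensitivity
    analysis with beta/gamma/lognormal parameter distributions, and an
    individual-level microsimulation used as a Monte-Carlo oracle for the
    cohort expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
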