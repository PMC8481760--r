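Package: smartsim
Title: Microsimulation of SMART and Multi-Arm RCT Designs for Sequencing
    Telemedicine Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo microsimulation comparing a two-stage Sequential
    Multiple Assignment Randomized Trial (SMART) with a comparable four-arm
    randomized controlled trial (RCT) for sequencing two telemedicine
    interventions (a self-titration smartphone app and a nurse telephone
    service) that support insulin initiation in type 2 diabetes. Provides a
    synthetic-patient generative model (truncated-normal baseline HbA1c,
    latent receptiveness, stage-wise HbA1c change), trial engines for both
    designs, inverse-probability-weighted estimation of the four embedded
    adaptive interventions, a configurable per-subject trial cost model, and
    experiment runners for base-case tables, sample-size sweeps, and
    responder-threshold sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
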