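Package: shhadapt
Title: Adaptation Dynamics of Sonic Hedgehog Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantifies the dynamics of Sonic Hedgehog (Shh)
    signalling in the vertebrate neural tube. Provides a thermodynamic
    promoter-occupancy model of Gli-mediated gene regulation, an ODE model
    of the Ptch1/Gli pathway with four wiring variants that isolate
    alternative adaptation mechanisms, approximate Bayesian computation by
    sequential Monte Carlo (ABC-SMC) against an integer adaptation-scoring
    distance, quantification of spatial morphogen gradients (exponential
    amplitude/decay-length fits, staging, binning, stereotyping into ramp
    inputs), and a calibrated synthetic-data generator so the whole
    analysis is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
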