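Package: spikempc
Title: Real-Time Spike Inference from Calcium Imaging via Model Predictive Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers neuronal firing rates from fluorescent calcium-indicator
    recordings by treating the firing rate as the unknown control input of a
    mass-action ordinary differential equation model of calcium/indicator
    binding, and recovering it with receding-horizon model predictive control.
    Includes the deterministic reaction-network model with steady-state and
    stability analysis, a shifted-sigmoid measurement filter with saturation
    fallback, auto-calibration of the firing gain from paired
    fluorescence/electrophysiology recordings, spikefinder-style CSV input and
    output, evaluation metrics (binned Pearson correlation and the
    Victor-Purpura spike-train distance), indicator frequency-response
    analysis, and a seeded synthetic-recording generator.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
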