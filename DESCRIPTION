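Package: bhrobust
Title: Robust Breath-Hold Lung SBRT Planning and Probabilistic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates breath-hold tumor-position reproducibility for lung
    stereotactic body radiotherapy (SBRT) and compares robust photon and proton
    planning strategies on a synthetic thorax phantom. Breath-hold variability is
    modelled with Laplacian (harmonic) displacement vector fields constrained by
    the lung wall; plans are built with scenario-based minimax robust optimization
    over discrete setup, breath-hold and stopping-power-ratio perturbations using
    simplified analytic photon and proton pencil-beam dose engines; and every plan
    is evaluated probabilistically by sampling simulated treatments from a
    hierarchical systematic/random error model, accumulating dose on the reference
    geometry, and summarising dose-volume-histogram metrics with 90%-probability
    (p90%) statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
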