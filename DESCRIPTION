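Package: vrplace
Title: Position-Correlated Cell Analysis for Virtual-Reality Calcium Imaging
Version: 0.1.0
Authors@R:
    person("VR Place Coding", "Maintainers", email = "maintainers@vrplace.invalid",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for two-photon calcium imaging
    sessions recorded while head-fixed mice run on circular virtual-reality
    tracks. Provides neuropil-corrected dF/F with a running-minimum baseline,
    velocity-gated occupancy-normalized position binning, a three-step place
    field criterion for classifying position-correlated cells, spatial
    information and sparsity with circular-shift shuffles, Bayesian population
    decoding of position with leave-one-lap-out cross-validation, population
    vector correlation and lap-wise field dynamics, global and rate remapping
    statistics, object-versus-position tuning classification with a
    shuffle-based double criterion, lick-precision behavioral scoring, and a
    fully seeded synthetic session generator that plants ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
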