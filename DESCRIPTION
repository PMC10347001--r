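Package: dpfgait
Title: Gait Phase Recognition from Wearable IMU Signals with
    Phase-Sequenced LSTM-CNN Model Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for four-phase gait recognition from lower-limb inertial
    measurement unit (IMU) joint-angle signals. Provides a seeded synthetic
    gait generator (multi-site joint angles plus bilateral plantar ground
    reaction force with exact phase ground truth), preprocessing (linear
    interpolation of dropped samples, min-max normalization to [-1, 1],
    sliding-window segmentation, sensor-group channel selection),
    ground-reaction-force threshold labeling of the four gait phases, a
    hybrid two-layer LSTM / two-layer CNN window classifier trained with
    Adam on cross-entropy, a phase-sequence-driven model-switching
    inference engine with debounced commits, macro-averaged evaluation
    metrics, and desk-scale experiment harnesses for sensor-placement
    ablation and paired method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
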