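Package: ankleguard
Title: Adaptive Ensemble Sizing for Real-Time Ankle Injury Risk Detection
    from Wearable Inertial Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates, preprocesses and analyses bilateral ankle-mounted
    inertial measurement unit (IMU) streams for proactive ankle-injury risk
    detection. Implements a hybrid ensemble of a quantized depthwise-separable
    1D convolutional network and a magnitude-pruned two-layer LSTM, whose
    mixing coefficient and pruning ratio are selected online by a Q-learning
    agent informed by a Gaussian-process motion forecaster with a composite
    Matern-3/2 plus periodic kernel. Includes a seeded synthetic motion
    generator covering six athletic scenarios, the full signal-conditioning
    chain (calibration, zero-phase Butterworth filtering, complementary-filter
    gravity removal, resampling, windowing, SMOTE rebalancing), lead-time
    detection metrics (injury detection accuracy, false alarm rate, advance
    prediction accuracy), ablation modes, and an accuracy-latency trade-off
    sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
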