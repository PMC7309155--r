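Package: gaitrisk
Title: Fall-Risk Prediction from Wearable IMU Gait Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting fall risk in elderly adults from lumbar
    inertial measurement unit (IMU) recordings taken during a six-minute
    walking test, combined with the Timed Up and Go (TUG) clinical test.
    Computes per-channel gait variability indices (standard deviation and
    box-counting fractal dimension of the six acceleration and angular
    velocity channels), fits a Youden-index TUG threshold classifier, an
    augmented TUG+ decision rule fusing the TUG time with two variability
    indices, a logistic-regression fusion variant, and a windowed
    convolutional neural network classifier on the raw signals. Includes
    diagnostic-test evaluation (sensitivity, specificity, likelihood
    ratios, McNemar comparison) and a calibrated synthetic gait cohort
    generator for end-to-end testing.
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
    pillar,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
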