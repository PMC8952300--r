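Package: gaitharmonics
Title: Harmonic Modeling, Prediction and Classification of Human Gait from a Thigh-Mounted IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonic (Fourier-series) modeling of thigh
    flexion-extension and sagittal gyro signals during level walking,
    recorded by a single thigh-mounted inertial measurement unit (IMU).
    Provides gyro-integration orientation filtering with accelerometer
    drift correction, stride segmentation at thigh-angle minima (toe-off),
    FFT-based harmonic extraction with stride cascading, waveform
    reconstruction and full-trial prediction, template-based stride
    classification against a bundled library of six thigh-angle and six
    gyro stride-pattern models, and a labeled synthetic gait generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
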