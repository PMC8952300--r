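# gaitharmonics

Harmonic modeling, prediction and classification of human gait from a
single thigh-mounted IMU.

## What this package does

During level walking the thigh's flexion–extension angle is periodic, one
period per stride (toe-off to toe-off). That makes it a natural fit for a
truncated Fourier series — the *harmonic model*

```
y(t) = b + Σ_{n=1..N} a_n · cos(2π n f0 t + φ_n)
```

where `f0` is the stride (fundamental) frequency, `a_n` and `φ_n` the
amplitude and initial phase of the n-th harmonic, and `b` the DC offset.
Five harmonics suffice to regenerate the thigh-angle waveform of a stride
with correlation above 0.999 and RMSE below 0.5°; the faster-moving sagittal
gyro signal needs nine.

The package implements the full pipeline around that model, for people
working on wearable-sensor gait analysis, rehabilitation monitoring and
pedestrian navigation:

- **Orientation**: single-axis thigh-angle estimation from raw 6-axis IMU
  data by gyro integration with accelerometer drift correction at
  quasi-static instants (`estimate_thigh_angle()`).
- **Stride segmentation**: toe-off detection at thigh-angle minima and at
  positive-gradient gyro zero crossings; minimum-to-minimum stride cropping
  with first/last stride exclusion (`segment_strides()`, `detect_toe_off()`).
- **Spectral extraction**: FFT spectrum with transform length equal to the
  record length, fundamental = highest peak, per-harmonic amplitude/phase
  pick-up, 4-fold stride cascading for finer bin spacing, and the 1 %-median
  significance rule (`compute_spectrum()`, `extract_harmonics()`,
  `fit_stride_model()`, `significant_harmonic_count()`).
- **A bundled model library**: published harmonic coefficients of the six
  most common level-walking stride patterns, for thigh angle (5 harmonics)
  and gyro (9 harmonics) (`load_model_library()`).
- **Prediction and classification**: regenerate a whole trial from the
  first stride's model, and classify every stride against the six pattern
  templates by Pearson correlation and RMSE matrices (`predict_trial()`,
  `classify_strides()`).
- **Synthetic gait generation**: labeled angle/gyro trials and raw IMU
  streams with controlled pattern mixture, stride-time jitter, residual
  harmonics and noise, so the whole pipeline is testable without any
  recordings (`simulate_trial()`, `simulate_imu()`).

## Worked example

Simulate a 12-stride walk mixing stride patterns 1 and 3, segment it,
fit a harmonic model to the first stride, predict the rest of the trial
from it, and classify every stride:

```r
library(gaitharmonics)

lib    <- load_model_library()
cfg    <- gait_sim_config(n_strides = 12, pattern_sequence = c(1, 3), seed = 42)
trial  <- simulate_trial(cfg, lib)
strides <- segment_strides(trial$angle, trial$gyro_dps)
length(strides)
#> [1] 10     # 12 strides minus the excluded first and last

first <- strides[[1]]
model <- fit_stride_model(first$angle_deg, rate_hz = 100, n_harmonics = 5,
                          f0_hz = stride_frequency_from_time(first$stride_time_s))
model
#> <harmonic_model> thigh_angle_deg, f0 = 1.02041 Hz, N = 5, b = 6.74777
#>  n  amplitude phase_rad
#>  1 18.8665130  3.487197
#>  2  3.9720705  2.972418
#>  3  1.4369500  1.326330
#>  4  0.4838940  3.582227
#>  5  0.4091788  1.516604

pred <- predict_trial(strides, model)
sprintf("trial correlation %.4f, RMSE %.3f deg", pred$correlation, pred$rmse_deg)
#> "trial correlation 0.9903, RMSE 1.964 deg"

classify_strides(strides, lib, channel = "angle")
#> <classification_matrix> 10 strides x 6 models (angle channel)
#> best model per stride: 3 1 3 1 3 1 3 1 1 1
#> correlation/RMSE disagreement on strides: 5
```

The fitted model's normalized overtone amplitudes (`a_n / a_1`: 0.21, 0.076,
0.026, 0.022) sit close to the bundled pattern-1/3 coefficients, the
first-stride model regenerates the 12-second trial to 0.99 correlation even
though half the strides follow a different pattern, and classification
recovers the generating pattern for 9 of the 10 interior strides (stride 9,
a pattern-3 stride, is attributed to the closely related pattern 1).

A command-line wrapper over the same functions ships in
`inst/cli/gaitharmonics` (subcommands `simulate`, `angle`, `segment`,
`model`, `reconstruct`, `classify`, `predict`).

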