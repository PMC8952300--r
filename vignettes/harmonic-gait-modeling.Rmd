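---
title: "Harmonic modeling of thigh-mounted IMU gait signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic modeling of thigh-mounted IMU gait signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitharmonics)
```

## The model

During steady level walking the thigh flexion–extension angle is periodic
with one period per stride, so the package represents one stride cycle of a
signal $y$ (thigh angle in degrees, or sagittal angular rate in °/s) as a
truncated Fourier series,

$$y(t) = b + \sum_{n=1}^{N} a_n \cos(2\pi n f_0 t + \varphi_n),$$

with fundamental (stride) frequency $f_0$, harmonic amplitudes $a_n$,
initial phases $\varphi_n$ (cosine convention, radians) and DC offset $b$.
The central empirical facts the package is built around:

- five harmonics regenerate a thigh-angle stride essentially losslessly
  (correlation $> 0.999$, RMSE $< 0.5$° per stride);
- the gyro signal, being the angle's derivative, tilts energy toward high
  harmonics and needs nine;
- $f_0$ can be estimated either as the highest-amplitude FFT peak or as the
  reciprocal of the stride time — the two agree to a small fraction of a
  percent, so the cheap stride-time estimate is the default in per-stride
  fitting.

The `harmonic_model` object carries exactly $(b, f_0, a_{1..N},
\varphi_{1..N})$; `reconstruct()` evaluates the series on a `time_grid`.

## The bundled stride-pattern library

Six commonly observed level-walking stride patterns are shipped as harmonic
coefficient files (`inst/extdata/thigh_models.json`, `gyro_models.json`),
six thigh-angle models with $N = 5$ and six gyro models with $N = 9$,
amplitudes normalized to the fundamental ($a_1 = 1$). The patterns grade
from no visible loading-response oscillation (pattern 1) to a secondary
peak nearly as strong as the main swing peak (pattern 6).

Two conventions had to be fixed because normalized coefficient tables
cannot carry them:

- **DC term.** Classification and prediction always rescale waveforms
  affinely before comparing, so any choice of $b$ within the affine class
  is equivalent. Templates are materialized with $b$ such that the
  one-period minimum is 0, consistent with the $[0, 1]$
  amplitude-normalization used for stride templates.
- **Time origin.** Measured strides are cropped minimum-to-minimum
  (toe-off to toe-off). `aligned_harmonic_model()` therefore shifts a
  model's time origin to its toe-off instant: the waveform minimum for the
  angle channel, and the upward zero crossing of the waveform about its
  midline for the gyro channel (the same instant — the angle's minimum is
  where its derivative crosses zero going up). The published phases turn
  out to encode this alignment already: the shifts come out at 0–0.3 % of
  a period for all twelve models, confirming the convention. For gyro
  patterns with strong loading-response oscillation there are several
  upward crossings per period; the one circularly nearest $t = 0$ is the
  toe-off crossing, and choosing "the first crossing" instead would
  misalign two of the six gyro templates by roughly half a period.

## Spectral extraction

`compute_spectrum()` uses the FFT with transform length equal to the input
length — deliberately *not* padded to a power of two, so that a signal
containing an integer number of periods puts every harmonic exactly on a
bin. Amplitudes are one-sided, $2|X_k|/L$ ($|X_0|/L$ for DC), phases are
the complex angle at the bin: with this calibration the spectrum of
$A\cos(2\pi f t + \varphi)$ over integer periods reads $A$ and $\varphi$
directly, so extracted coefficients drop straight into the harmonic model.
A Parseval identity ties the calibration down in the tests at $10^{-9}$
relative error.

Per-stride fitting (`fit_stride_model()`) first cascades the stride four
times (`cascade_for_fft()`): repetition leaves the harmonic content
untouched but quadruples the record length, refining the bin spacing so
that harmonic $n$ of a stride of $L$ samples lands exactly on bin $4n$.
`extract_harmonics()` reads each harmonic at the local amplitude maximum
within ±1 bin of the nearest bin to $n f_0$, which tolerates a fundamental
slightly off the grid; no sub-bin interpolation is performed — for
minimum-cropped strides the fundamental is on-grid by construction, and
the ±1-bin search absorbs the residual cases.

The number of harmonics worth keeping is decided by the 1 %-median rule
(`significant_harmonic_count()`): harmonic $n$ is significant while the
median of $a_n/a_1$ across strides stays at or above 0.01. Applied to the
six bundled thigh-angle coefficient rows this yields 5, matching the
population-level finding. A caveat worth recording: applied to the six
*gyro* rows alone the rule yields 8, because the ninth harmonic's median
across just these six templates is ≈ 0.003. The nine-harmonic figure for
gyro signals comes from a large stride population, not from the six
template rows, and the package keeps 9 as the gyro default
(`pipeline_config()$n_harmonics_gyro`).

## Segmentation

Toe-off minima are detected with a prominence filter: a minimum counts only
if the lower of the two barriers separating it from a deeper value is at
least 20 % of the trial's amplitude range (default), with a minimum spacing
of 0.4 s. The prominence threshold is what keeps the loading-response dip
of patterns 4–6 (prominence ≈ 7–13 % of range on the templates) from
splitting strides, while toe-off minima have near-total prominence. One
non-obvious convention: a side of a candidate minimum that reaches the
signal edge without encountering a deeper value is treated as an *open*
(infinite) barrier rather than being capped at the edge. This keeps the
boundary minima of a walk detectable — under measurement noise the last
toe-off minimum otherwise collapses to near-zero prominence simply because
the recording ends — and any spurious edge minima this admits fall into the
first or last segment, which the segmentation excludes as
gait-initiation/termination transients anyway.

Strides are half-open intervals $[\min_k, \min_{k+1})$, so consecutive
strides share the boundary sample without duplicating it. Normalization
(`normalize_stride()`) resamples to 2000 points by linear interpolation on
normalized time (stride time mapped to 1 s) and maps the amplitude to
$[0, 1]$. Template grouping (`group_by_template()`) admits a stride to its
lowest-RMSE template when that RMSE is below 2.5 % on the normalized scale;
an exact copy (RMSE 0) is admitted at any cutoff, which is what makes the
zero-cutoff behavior "exact copies only". Mean templates are normalized
both before and after averaging: inputs are unit-range by construction and
the sample-wise mean is re-normalized so the result is again a valid
template — averaging can only shrink the range, so re-normalization is the
conservative choice and is affinely neutral for all downstream comparisons.

## Prediction and classification

`predict_trial()` regenerates every stride of a trial from one harmonic
model: per stride, $f_0$ is re-estimated as the reciprocal stride time and
the amplitude is rescaled. Two rescaling rules exist in the literature of
this pipeline; the package defaults to matching the stride's measured
peak-to-peak range (`rescale = "peak_to_peak"`) and offers scaling the
fundamental amplitude to the stride's maximum angle
(`rescale = "max_as_a1"`) as an option, because the peak-to-peak rule is
the one that leaves correlation unaffected and bounds RMSE.

`classify_strides()` compares each stride against all six library models
(angle or gyro channel) at the stride's own $f_0$ and grid, after affine
rescaling to the stride's range. "Correlation" is Pearson's product-moment
coefficient — the standard waveform-similarity choice, consistent with
reported values like 0.997. Both stride and template start at toe-off by
construction, so no lag search is needed; segmentation error of a sample or
two is visible as occasional confusion between adjacent patterns. The best
model is the correlation argmax (ties to the lower model index); the RMSE
argmin is recorded alongside with a disagreement flag, correlation winning
because it is scale-free.

## The synthetic generator

`simulate_trial()` emulates the structure of a level-walking trial measured
by a 100 Hz thigh-mounted IMU. Its defaults *are* the study conditions and
are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `stride_time_mean_s` | 1.0 s | normal self-selected cadence, ≈ 2 steps/s |
| `stride_time_cv` | 0.03 | healthy-gait stride-time variability of a few percent |
| `angle_range_deg` | (−15°, 25°) | typical 40° flexion–extension excursion |
| `noise_deg_sd` | 0.3° | angle-estimate noise at 100 Hz |
| `extra_harmonic_frac` | 0.005 | sub-1 % residual overtone tail (harmonics 6–10, random phases) |
| `gyro_noise_dps_sd` | 0.5 °/s | consumer MEMS gyro noise |
| `accel_noise_g_sd` | 0.005 g | consumer MEMS accelerometer noise |
| `gyro_bias_dps` | 0 | bias is switched on explicitly in drift studies |

Each stride is a toe-off-aligned library model evaluated analytically at
the stride's jittered $f_0$ (lognormal jitter, for positivity), rescaled to
the angle range; the gyro channel is the *analytic* derivative of the
noiseless angle, so generator and orientation module are exact inverses up
to noise. Strides join at the shared boundary minimum and a closing
boundary sample ends the trial. Ground-truth labels, boundaries and
per-stride fundamentals always accompany the output; every accuracy claim
in the test suite is computed against them.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: soft-tissue artifact, sensor mounting slip,
gait-initiation/termination transients (the simulated trial is steady-state
from the first stride), within-stride waveform morphing between patterns,
non-white sensor noise, and linear body acceleration in the accelerometer
channels (the simulated accelerometer sees only rotated gravity plus white
noise, which makes quasi-static detection easier than in reality).

`simulate_imu()` inverts the orientation model: sagittal gyro =
differentiated angle + bias + noise; accelerometer = gravity rotated by the
angle in the sagittal plane + noise.

## Orientation filtering

`estimate_thigh_angle()` implements a deliberately minimal single-axis
gyro-integration filter with accelerometer drift correction: trapezoidal
integration of the sagittal rate, and at each quasi-static sample
($\bigl|\;\lVert a\rVert - 1\,g\;\bigr| \le$ `quasi_static_tol`, default
0.05 g) a complementary blend
$\theta \leftarrow (1-\alpha)\,\theta + \alpha\,\theta_{acc}$ with
$\theta_{acc} = \operatorname{atan2}(a_x, a_z)$ and $\alpha = 0.02$ per
sample. With a constant gyro bias $b_\omega$ and corrections at every
sample the steady-state error is $\approx b_\omega \Delta t / \alpha$
(0.25° at 0.5 °/s bias, 100 Hz), i.e. drift is bounded instead of growing
linearly. This filter is a minimal stand-in for a full orientation filter
and is validated by parameter recovery on synthetic data only (angle RMSE
< 1° over a 20 s biased walk); it is not a contribution of the package and
full 3-D orientation estimation is out of scope.

## Numerical choices and degenerate inputs

- FFT length = input length, never padded; one-sided amplitude calibration
  as above; phases wrapped to $[0, 2\pi)$ to match the published phase
  convention.
- Fundamental ties (two equal maximal bins) break toward the lower
  frequency; `find_fundamental()` is invariant under positive scaling.
- Median over an even number of strides is the mean of the central values
  (base R `median`).
- Constant signals are rejected wherever a range or correlation is needed
  (`normalize_to_unit_range()`, `pearson_correlation()`), with typed
  errors; degenerate strides inside `predict_trial()` are skipped with a
  log message rather than aborting the trial.
- Zero-crossing times are linearly interpolated between bracketing samples;
  the gradient check uses central differences, and the first qualifying
  crossing wins.
- All randomness flows through explicit seeds (`gait_sim_config(seed = )`,
  CLI `--seed`); fixed-seed runs are bit-identical.

## Validation problem sizes

The test suite and the acceptance script run entirely on synthesized data:
coefficient round trips use 4 periods at 100 Hz (400 samples); the
regeneration study uses 200 strides across all six patterns; classification
robustness uses 600 noisy strides; orientation recovery uses 20 s trials.
These sizes were chosen to make the statistics stable (medians over ≥ 200
strides, proportions over 600) while keeping a full run in the
tens-of-seconds range on a single core.

## Known limitations

- The stride-pattern library covers level walking only; no coefficients
  are bundled for stairs or ramps, and activity recognition is out of
  scope.
- The orientation filter is single-axis and assumes a mostly sagittal
  rotation with a known gyro axis; no magnetometer fusion.
- Classification accuracy between adjacent patterns (e.g. 3 vs. 4) is
  intrinsically limited by their high template correlation (> 0.99 for
  some gyro pairs); with realistic noise a few percent of strides land on
  a neighboring pattern.
- Real recordings of the original study are not publicly available, so all
  quantitative claims are validated by construction on synthetic data plus
  the published coefficient tables.
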