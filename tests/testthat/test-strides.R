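noiseless_cfg <- function(n, patterns = 1L, seed = 1) {
  gait_sim_config(n_strides = n, pattern_sequence = patterns,
                  stride_time_cv = 0, noise_deg_sd = 0,
                  extra_harmonic_frac = 0, gyro_noise_dps_sd = 0, seed = seed)
}

test_that("segmentation crops interior strides between angle minima", {
  trial <- simulate_trial(noiseless_cfg(10), gait_lib)
  st <- segment_strides(trial$angle, trial$gyro_dps)
  expect_length(st, 8)
  lens <- vapply(st, function(s) length(s$angle_deg), integer(1))
  expect_lte(diff(range(lens)), 1)                 # identical durations +/- 1 sample
  expect_equal(vapply(st, `[[`, numeric(1), "stride_time_s"),
               rep(1, 8), tolerance = 0.02)
  expect_false(any(vapply(st, function(s) is.null(s$gyro_dps), logical(1))))

  # works under realistic noise and jitter too, for every pattern
  trial2 <- simulate_trial(gait_sim_config(n_strides = 12,
                                           pattern_sequence = 1:6, seed = 8),
                           gait_lib)
  st2 <- segment_strides(trial2$angle)
  expect_length(st2, 10)
})

test_that("segmentation rejects degenerate trials and boundary-only trials", {
  flat <- thigh_angle_series((0:499) / 100, rep(3, 500), "direct")
  expect_error(segment_strides(flat), "insufficient strides")
  two <- simulate_trial(noiseless_cfg(2), gait_lib)
  expect_length(segment_strides(two$angle), 0)     # both strides are boundary strides
})

test_that("toe-off is the interpolated positive-gradient gyro zero crossing", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(detect_toe_off(-sin(2 * pi * t), t), 0.5, tolerance = 1e-6)
  expect_error(detect_toe_off(2 + sin(2 * pi * t), t), "not found")

  # against a bisection root of the analytic gyro model 1 waveform
  m <- aligned_harmonic_model(gait_lib$gyro_models[[1]], "gyro")
  f <- function(tt) reconstruct(m, tt) - m$dc_offset
  tt <- seq(0.05, 1.05, by = 0.01)                 # skip the crossing at t = 0
  got <- detect_toe_off(f(tt), tt)
  dense <- seq(0.05, 1.05, by = 1e-5)
  vals <- f(dense)
  ups <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  root <- stats::uniroot(f, c(dense[ups[1]], dense[ups[1] + 1]), tol = 1e-12)$root
  expect_equal(got, root, tolerance = 1e-3)
})

test_that("stride frequency is the reciprocal stride time and matches the FFT", {
  expect_equal(stride_frequency_from_time(1.0), 1.0)
  expect_equal(stride_frequency_from_time(1.25), 0.8)
  expect_error(stride_frequency_from_time(0), "> 0")

  # synthetic stride at 0.925 Hz: both estimators land within one FFT bin
  cfg <- gait_sim_config(n_strides = 5, stride_time_mean_s = 1 / 0.925,
                         stride_time_cv = 0, noise_deg_sd = 0,
                         extra_harmonic_frac = 0, seed = 2)
  st <- trial_true_strides(simulate_trial(cfg, gait_lib))[[3]]
  f_time <- stride_frequency_from_time(st$stride_time_s)
  casc <- cascade_for_fft(st$angle_deg, 4)
  spec <- compute_spectrum(casc, st$rate_hz)
  f_fft <- find_fundamental(spec)$f0_hz
  expect_lt(abs(f_fft - f_time), spec$freqs_hz[1] + 1e-12)
  expect_equal(f_time, 0.925, tolerance = 0.005)
})

test_that("cascading repeats the stride and moves the fundamental to bin 4", {
  expect_identical(cascade_for_fft(c(1, 2), 4), rep(c(1, 2), 4))
  expect_identical(cascade_for_fft(c(1, 2, 3), 1), c(1, 2, 3))
  expect_error(cascade_for_fft(numeric(0)), "empty")

  st <- trial_true_strides(simulate_trial(noiseless_cfg(4), gait_lib))[[2]]
  spec <- compute_spectrum(cascade_for_fft(st$angle_deg, 4), st$rate_hz)
  expect_identical(find_fundamental(spec)$bin, 4L)
})

test_that("stride normalization resamples to 2000 unit-range points", {
  st <- trial_true_strides(simulate_trial(noiseless_cfg(4), gait_lib))[[2]]
  ns <- normalize_stride(st)
  expect_length(ns$samples, 2000)
  expect_equal(min(ns$samples), 0)
  expect_equal(max(ns$samples), 1)
  expect_equal(ns$original_range, range(st$angle_deg))

  # a stride already at 2000 uniform points only gets amplitude-normalized
  x <- seq(0, 4, length.out = 2000)
  expect_equal(normalize_stride(x)$samples, (x - 0) / 4, tolerance = 1e-12)

  # template shape survives the round trip
  tpl <- model_template(gait_lib$thigh_models[[5]], 2000)
  st5 <- trial_true_strides(simulate_trial(noiseless_cfg(4, patterns = 5L),
                                           gait_lib))[[2]]
  expect_gt(pearson_correlation(normalize_stride(st5)$samples, tpl), 1 - 1e-6)

  expect_error(normalize_stride(rep(1, 50)), "degenerate")
})

test_that("strides group to the nearest template under the 2.5% RMSE rule", {
  templates <- lapply(gait_lib$thigh_models, model_template, n_points = 500)
  g0 <- group_by_template(templates[1], templates)
  expect_identical(g0$assignment, 1L)
  expect_equal(g0$rmse[1, 1], 0)

  # uniform offset of 0.05 -> RMSE 0.05, above the cutoff, unassigned
  shifted <- list(templates[[1]] + 0.05)
  expect_identical(group_by_template(shifted, templates)$assignment, NA_integer_)

  # zero cutoff accepts only exact copies
  near <- list(templates[[2]], templates[[2]] + 1e-9)
  z <- group_by_template(near, templates, rmse_cutoff = 0)
  expect_identical(z$assignment, c(2L, NA_integer_))

  set.seed(31)
  noisy <- lapply(rep(1:6, each = 20), function(j) {
    templates[[j]] + stats::rnorm(500, 0, 0.01)
  })
  res <- group_by_template(noisy, templates)
  hit <- mean(res$assignment == rep(1:6, each = 20), na.rm = FALSE)
  expect_gte(hit, 0.95)
})

test_that("mean templates converge to the generating waveform", {
  tpl <- model_template(gait_lib$thigh_models[[3]], 400)
  one <- mean_template(list(tpl))
  expect_equal(one$samples, tpl)

  mirror <- mean_template(list(tpl + 0.1, tpl - 0.1))
  expect_equal(mirror$samples, (tpl - min(tpl)) / diff(range(tpl)))

  set.seed(17)
  noisy <- lapply(1:50, function(i) tpl + stats::rnorm(400, 0, 0.02))
  mt <- mean_template(noisy)
  expect_gt(pearson_correlation(mt$samples, tpl), 0.999)

  expect_error(mean_template(list()), "empty")
})
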