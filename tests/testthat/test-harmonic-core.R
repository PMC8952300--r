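test_that("reconstruct evaluates the cosine series exactly", {
  m <- harmonic_model(0, 1, amplitudes = 1, phases = 0)
  expect_equal(reconstruct(m, c(0, 0.25, 0.5)), c(1, 0, -1))

  dc_only <- harmonic_model(0.3, 1, amplitudes = 0, phases = 0)
  expect_equal(reconstruct(dc_only, time_grid(duration_s = 1, rate_hz = 10)),
               rep(0.3, 10))

  # library model 1 at t = 0 against an independent term-by-term summation
  m1 <- aligned_harmonic_model(gait_lib$thigh_models[[1]], "angle")
  by_hand <- m1$dc_offset + sum(m1$amplitudes * cos(m1$phases))
  expect_equal(reconstruct(m1, 0), by_hand)
})

test_that("reconstruct rejects invalid models and grids", {
  expect_error(harmonic_model(0, -1, 1, 0), "positive")
  expect_error(harmonic_model(0, 1, numeric(0), numeric(0)), "at least one")
  expect_error(harmonic_model(0, 1, c(1, 0.5), 0), "equal length")
  expect_error(time_grid(duration_s = 0), "> 0")
})

test_that("reconstruction is linear in the model and periodic in f0", {
  set.seed(42)
  g <- time_grid(duration_s = 2, rate_hz = 100)
  for (i in 1:5) {
    m1 <- random_model(); m2 <- random_model()
    # phasor addition per harmonic
    z <- m1$amplitudes * exp(1i * m1$phases) + m2$amplitudes * exp(1i * m2$phases)
    msum <- harmonic_model(m1$dc_offset + m2$dc_offset, 1, Mod(z), Arg(z) %% (2 * pi),
                           signal_kind = "normalized")
    expect_equal(reconstruct(msum, g),
                 reconstruct(m1, g) + reconstruct(m2, g), tolerance = 1e-12)

    y <- reconstruct(m1, time_grid(duration_s = 3, rate_hz = 100))
    expect_equal(y[1:100], y[101:200], tolerance = 1e-10)
    expect_equal(y[1:100], y[201:300], tolerance = 1e-10)
  }
})

test_that("unit-range normalization maps extrema to 0 and 1 and inverts exactly", {
  n <- normalize_to_unit_range(c(2, 4, 6))
  expect_equal(n$normalized, c(0, 0.5, 1))
  expect_equal(n$offset, 2)
  expect_equal(n$scale, 4)

  idn <- normalize_to_unit_range(c(0, 0.25, 1))
  expect_equal(idn$normalized, c(0, 0.25, 1))
  expect_equal(idn$offset, 0)
  expect_equal(idn$scale, 1)

  set.seed(7)
  x <- stats::rnorm(200, sd = 20)
  n <- normalize_to_unit_range(x)
  expect_equal(n$normalized * n$scale + n$offset, x,
               tolerance = 1e-12 * n$scale)

  expect_error(normalize_to_unit_range(rep(1, 5)), "degenerate")
  expect_error(normalize_to_unit_range(3), "at least 2")
})

test_that("rescale_to_reference matches the reference extrema, preserving shape", {
  expect_equal(rescale_to_reference(c(0, 0.5, 1), c(-10, 25, 30)), c(-10, 10, 30))
  x <- c(0, 0.3, 1, 0.2)
  expect_equal(rescale_to_reference(x, x), x)
  expect_error(rescale_to_reference(c(0, 1), c(2, 2)), "degenerate")

  # model-6 template against a synthetic stride of known extrema
  tpl <- model_template(gait_lib$thigh_models[[6]], 500)
  ref <- tpl * 38 - 12 + stats::rnorm(500, 0, 0.1)
  out <- rescale_to_reference(tpl, ref)
  expect_equal(min(out), min(ref))
  expect_equal(max(out), max(ref))

  # affine invariance: correlation with a third signal is unchanged
  set.seed(11)
  third <- stats::rnorm(500)
  expect_equal(pearson_correlation(out, third), pearson_correlation(tpl, third),
               tolerance = 1e-12)
})

test_that("the bundled model library reproduces the published coefficients", {
  lib <- gait_lib
  expect_length(lib$thigh_models, 6)
  expect_length(lib$gyro_models, 6)
  expect_identical(lib$labels, 1:6)
  expect_identical(lib$thigh_models[[1]]$amplitudes[2], 0.18150)
  expect_identical(lib$gyro_models[[5]]$amplitudes[9], 0.000666)
  expect_identical(lib$thigh_models[[6]]$phases[1], 3.4515)
  for (m in lib$thigh_models) {
    expect_identical(m$amplitudes[1], 1)
    expect_identical(m$n_harmonics, 5L)
    expect_identical(m$signal_kind, "normalized")
  }
  for (m in lib$gyro_models) {
    expect_identical(m$amplitudes[1], 1)
    expect_identical(m$n_harmonics, 9L)
  }
  expect_error(load_model_library(tempdir()), "not found")
})

test_that("templates are unit-range and start at the toe-off sample", {
  for (j in 1:6) {
    tpl <- model_template(gait_lib$thigh_models[[j]], 2000)
    expect_length(tpl, 2000)
    expect_equal(min(tpl), 0)
    expect_equal(max(tpl), 1)
    expect_identical(which.min(tpl), 1L)  # angle template begins at its minimum
  }
  # gyro template starts at (or adjacent to) an upward zero crossing of the
  # raw waveform
  for (j in 1:6) {
    m <- aligned_harmonic_model(gait_lib$gyro_models[[j]], "gyro")
    raw <- reconstruct(m, (0:1999) / 2000) - m$dc_offset
    mid <- raw - mean(raw)
    expect_lt(abs(mid[1]), 0.05 * diff(range(mid)))
    expect_gt(mid[5] - mid[1], 0)  # rising
  }
})
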