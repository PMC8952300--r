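test_that("spectrum amplitude calibration recovers cosine amplitude and phase", {
  t <- (0:999) / 100
  spec <- compute_spectrum(2 * cos(2 * pi * 1 * t), 100)
  i <- which.min(abs(spec$freqs_hz - 1))
  expect_equal(spec$amplitudes[i], 2)
  # zero phase up to wrap-around at 2*pi
  expect_lt(min(abs(spec$phases_rad[i] - c(0, 2 * pi))), 1e-10)
  expect_equal(spec$n_input, 1000L)

  spec5 <- compute_spectrum(rep(5, 100), 100)
  expect_equal(spec5$dc, 5)
  expect_lt(max(spec5$amplitudes), 1e-12)

  expect_error(compute_spectrum(1:5, 100), "too short")
})

test_that("a 4-period library reconstruction concentrates on bins 4,8,12,16,20", {
  m2 <- aligned_harmonic_model(gait_lib$thigh_models[[2]], "angle")
  y <- reconstruct(m2, time_grid(duration_s = 4, rate_hz = 100))
  spec <- compute_spectrum(y, 100)
  nonzero <- which(spec$amplitudes > 1e-9)
  expect_identical(nonzero, c(4L, 8L, 12L, 16L, 20L))
})

test_that("the fundamental is the highest non-DC peak, ties to lower frequency", {
  t <- (0:999) / 100
  f <- find_fundamental(compute_spectrum(cos(2 * pi * 0.9 * t), 100))
  expect_equal(f$f0_hz, 0.9)

  # two exactly equal peaks -> lower frequency wins
  sp <- structure(list(freqs_hz = c(1, 2, 3), amplitudes = c(0.5, 0.5, 0.1),
                       phases_rad = c(0, 0, 0), dc = 0, n_input = 6,
                       rate_hz = 6), class = "spectrum_gait")
  expect_equal(find_fundamental(sp)$f0_hz, 1)

  # overtones never dominate a library model
  y <- reconstruct(aligned_harmonic_model(gait_lib$thigh_models[[1]], "angle"),
                   time_grid(duration_s = 4, rate_hz = 100))
  expect_equal(find_fundamental(compute_spectrum(y, 100))$f0_hz, 1)

  # invariance under positive scaling
  s1 <- compute_spectrum(y, 100); s2 <- compute_spectrum(7.3 * y, 100)
  expect_identical(find_fundamental(s1)$bin, find_fundamental(s2)$bin)

  expect_error(find_fundamental(compute_spectrum(rep(0, 64), 100)),
               "no fundamental")
})

test_that("harmonic extraction round-trips the published coefficients", {
  g <- time_grid(duration_s = 4, rate_hz = 100)

  m3 <- gait_lib$thigh_models[[3]]
  hs <- extract_harmonics(
    compute_spectrum(reconstruct(
      harmonic_model(0.9, 1, m3$amplitudes, m3$phases, "normalized"), g), 100),
    1, 5)
  expect_equal(hs$entries$amplitude[2], 0.20959, tolerance = 1e-6)
  expect_equal(hs$entries$phase_rad[2], 3.0176, tolerance = 1e-6)
  expect_equal(hs$dc, 0.9, tolerance = 1e-9)

  mg3 <- gait_lib$gyro_models[[3]]
  hsg <- extract_harmonics(
    compute_spectrum(reconstruct(
      harmonic_model(0, 1, mg3$amplitudes, mg3$phases, "normalized"), g), 100),
    1, 9)
  expect_equal(hsg$entries$amplitude[2], 0.42098, tolerance = 1e-6)

  # pure cosine: only the fundamental survives
  hs1 <- extract_harmonics(compute_spectrum(cos(2 * pi * (0:399) / 100), 100), 1, 3)
  expect_equal(hs1$entries$amplitude, c(1, 0, 0), tolerance = 1e-10)

  expect_error(extract_harmonics(compute_spectrum(cos(0:99), 100), 10, 9),
               "Nyquist")
})

test_that("extraction inverts reconstruction for random on-grid models", {
  set.seed(99)
  g <- time_grid(duration_s = 4, rate_hz = 100)
  for (i in 1:8) {
    m <- random_model(n_harmonics = sample(3:9, 1))
    hs <- extract_harmonics(compute_spectrum(reconstruct(m, g), 100),
                            1, m$n_harmonics)
    expect_equal(hs$entries$amplitude, m$amplitudes, tolerance = 1e-6)
    expect_equal(hs$entries$phase_rad, m$phases, tolerance = 1e-6)
    expect_equal(hs$dc, m$dc_offset, tolerance = 1e-9)
    m2 <- as_harmonic_model(hs, signal_kind = "normalized")
    expect_equal(reconstruct(m2, g), reconstruct(m, g), tolerance = 1e-8)
  }
})

test_that("one-sided amplitudes satisfy Parseval's identity on multi-tone input", {
  set.seed(5)
  t <- (0:799) / 100
  for (i in 1:4) {
    amps <- stats::runif(4, 0.5, 3)
    freqs <- sample(1:30, 4)                 # integer periods over 8 s grid
    dc <- stats::runif(1, -2, 2)
    y <- dc + colSums(amps * sin(outer(freqs, 2 * pi * t) + stats::runif(4)))
    spec <- compute_spectrum(y, 100)
    expect_equal(sum(spec$amplitudes^2) / 2 + spec$dc^2, mean(y^2),
                 tolerance = 1e-9 * mean(y^2))
  }
})

test_that("the 1% median rule counts significant harmonics", {
  rows <- do.call(rbind, lapply(gait_lib$thigh_models, `[[`, "amplitudes"))
  expect_identical(significant_harmonic_count(rows), 5L)
  # identical result when the table is padded with zero overtones
  expect_identical(significant_harmonic_count(cbind(rows, 0, 0, 0, 0)), 5L)

  expect_identical(significant_harmonic_count(matrix(c(1, 0.5), 1)), 2L)
  expect_identical(significant_harmonic_count(matrix(c(1, 0.005), 1)), 1L)
  # even row count: median is the mean of the central values
  even <- rbind(c(1, 0.004), c(1, 0.018))
  expect_identical(significant_harmonic_count(even), 2L)
  expect_error(significant_harmonic_count(matrix(numeric(0), 0, 2)), "at least one")
})
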