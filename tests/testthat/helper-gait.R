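# shared fixtures, built in code at test time

gait_lib <- load_model_library()

# strides synthesized directly from library templates on an L-sample grid,
# rescaled to a physical range; the generating label is the list index
make_template_strides <- function(library = gait_lib, channel = "angle",
                                  n_samples = 100L, range_lo = -15,
                                  range_hi = 25, noise_sd = 0) {
  models <- if (channel == "angle") library$thigh_models else library$gyro_models
  lapply(seq_along(models), function(j) {
    w <- model_template(models[[j]], n_points = 2000L, channel = channel)
    u <- (seq_len(n_samples) - 1L) / n_samples
    w <- stats::approx((seq_len(2000L) - 1L) / 2000L, w, xout = u, rule = 2)$y
    w <- w * (range_hi - range_lo) + range_lo
    if (noise_sd > 0) w <- w + stats::rnorm(n_samples, 0, noise_sd)
    if (channel == "angle") {
      stride(w, start_s = 0, end_s = n_samples / 100,
             rate_hz = 100, index_in_trial = j)
    } else {
      stride(rep(0, n_samples), gyro_dps = w, start_s = 0,
             end_s = n_samples / 100, rate_hz = 100, index_in_trial = j)
    }
  })
}

# random harmonic model for property-style loops (f0 on the FFT grid of a
# 4 s, 100 Hz record, harmonics well below Nyquist)
random_model <- function(n_harmonics = 5L, f0_hz = 1) {
  harmonic_model(stats::runif(1, -5, 5), f0_hz,
                 amplitudes = c(1, stats::runif(n_harmonics - 1L, 0, 0.5)),
                 phases = stats::runif(n_harmonics, 0, 2 * pi),
                 signal_kind = "normalized")
}
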