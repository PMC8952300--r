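#' Configuration for the synthetic gait generator
#'
#' Defines the conditions of a simulated level-walking trial: stride count
#' and pattern mixture, stride-time statistics, thigh-angle excursion,
#' measurement noise, and the residual high-harmonic content seen in real
#' spectra beyond the modeled harmonics.
#'
#' @param n_strides number of strides in the trial.
#' @param pattern_sequence stride-pattern labels (1-6); recycled round-robin
#'   to `n_strides` when shorter.
#' @param stride_time_mean_s mean stride time in seconds (default 1.0,
#'   normal self-selected cadence of about two steps per second).
#' @param stride_time_cv coefficient of variation of the lognormal
#'   stride-time jitter (default 0.03).
#' @param angle_range_deg thigh-angle excursion `(min, max)` in degrees
#'   (default `c(-15, 25)`, a 40 degree flexion-extension range).
#' @param noise_deg_sd white measurement noise on the angle, degrees SD
#'   (default 0.3).
#' @param extra_harmonic_frac amplitude of residual harmonics 6-10 as a
#'   fraction of the fundamental amplitude, with per-stride random phases
#'   (default 0.005, the sub-1-percent overtone tail of real spectra).
#' @param gyro_noise_dps_sd white gyro noise, deg/s SD (default 0.5).
#' @param accel_noise_g_sd white accelerometer noise, g SD (default 0.005).
#' @param gyro_bias_dps constant gyro bias in deg/s (default 0).
#' @param rate_hz sampling rate (default 100).
#' @param seed optional RNG seed for reproducible trials.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(n_strides = 10L,
                            pattern_sequence = 1L,
                            stride_time_mean_s = 1.0,
                            stride_time_cv = 0.03,
                            angle_range_deg = c(-15, 25),
                            noise_deg_sd = 0.3,
                            extra_harmonic_frac = 0.005,
                            gyro_noise_dps_sd = 0.5,
                            accel_noise_g_sd = 0.005,
                            gyro_bias_dps = 0,
                            rate_hz = 100,
                            seed = NULL) {
  if (n_strides < 1L) stop("`n_strides` must be >= 1", call. = FALSE)
  if (stride_time_mean_s <= 0) stop("`stride_time_mean_s` must be > 0", call. = FALSE)
  if (stride_time_cv < 0 || noise_deg_sd < 0 || extra_harmonic_frac < 0 ||
      gyro_noise_dps_sd < 0 || accel_noise_g_sd < 0) {
    stop("noise and jitter parameters must be >= 0", call. = FALSE)
  }
  if (length(angle_range_deg) != 2L || angle_range_deg[2] <= angle_range_deg[1]) {
    stop("`angle_range_deg` must be (min, max) with max > min", call. = FALSE)
  }
  if (!all(pattern_sequence %in% 1:6)) {
    stop("pattern labels must be in 1..6", call. = FALSE)
  }
  structure(list(n_strides = as.integer(n_strides),
                 pattern_sequence = as.integer(pattern_sequence),
                 stride_time_mean_s = stride_time_mean_s,
                 stride_time_cv = stride_time_cv,
                 angle_range_deg = as.numeric(angle_range_deg),
                 noise_deg_sd = noise_deg_sd,
                 extra_harmonic_frac = extra_harmonic_frac,
                 gyro_noise_dps_sd = gyro_noise_dps_sd,
                 accel_noise_g_sd = accel_noise_g_sd,
                 gyro_bias_dps = gyro_bias_dps,
                 rate_hz = rate_hz,
                 seed = seed),
            class = "gait_sim_config")
}

# analytic time-derivative of a harmonic model, as deg/s when the model is in deg
derivative_model_eval <- function(model, t) {
  n <- seq_len(model$n_harmonics)
  w <- 2 * pi * n * model$fundamental_hz
  arg <- outer(2 * pi * model$fundamental_hz * t, n) +
    matrix(model$phases, nrow = length(t), ncol = model$n_harmonics, byrow = TRUE)
  -as.numeric(sin(arg) %*% (model$amplitudes * w))
}

#' Simulate a labeled walking trial (thigh angle and gyro)
#'
#' Builds a continuous trial from the stride-pattern library: each stride is
#' a toe-off-aligned library model reconstruction, rescaled to the
#' configured thigh-angle range, with per-stride lognormal stride-time
#' jitter, residual harmonics 6-10 at random phases, and additive white
#' noise. The gyro channel is the analytic time-derivative of the noiseless
#' angle plus white gyro noise. Strides join at the shared boundary minimum,
#' and a closing boundary sample ends the trial so that segmentation sees
#' every stride's minima. Ground-truth labels, boundaries and per-stride
#' fundamentals are returned alongside the signals.
#'
#' @param config a [gait_sim_config()].
#' @param library a `model_library` (default: the bundled one).
#' @return A `gait_trial`: list with `angle` (a [thigh_angle_series()]),
#'   `gyro_dps`, `times_s`, and ground truth `labels`, `boundaries_s`,
#'   `f0_hz`, `stride_samples` plus the `config`.
#' @export
simulate_trial <- function(config, library = load_model_library()) {
  stopifnot(inherits(config, "gait_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  labels <- rep_len(config$pattern_sequence, config$n_strides)
  rate <- config$rate_hz
  lo <- config$angle_range_deg[1]; hi <- config$angle_range_deg[2]

  # per-pattern aligned models and their one-period peak-to-peak (unit-a1 scale)
  aligned <- lapply(library$thigh_models, aligned_harmonic_model, channel = "angle")
  pp_norm <- vapply(aligned, function(m) {
    t <- seq(0, 1, length.out = 2001L)[-2001L]
    diff(range(reconstruct(m, t)))
  }, numeric(1))

  # lognormal stride times with the configured mean and CV, snapped to the grid
  if (config$stride_time_cv > 0) {
    sdlog <- sqrt(log(1 + config$stride_time_cv^2))
    meanlog <- log(config$stride_time_mean_s) - sdlog^2 / 2
    stride_times <- stats::rlnorm(config$n_strides, meanlog, sdlog)
  } else {
    stride_times <- rep(config$stride_time_mean_s, config$n_strides)
  }
  stride_len <- pmax(4L, as.integer(round(stride_times * rate)))
  stride_times <- stride_len / rate

  angle <- numeric(0)
  gyro <- numeric(0)
  for (k in seq_len(config$n_strides)) {
    lab <- labels[k]
    L <- stride_len[k]
    f0 <- 1 / stride_times[k]
    m <- aligned[[lab]]
    mk <- harmonic_model(m$dc_offset, f0, m$amplitudes, m$phases,
                         signal_kind = "normalized", label = lab)
    t_local <- (seq_len(L) - 1L) / rate
    scale_deg <- (hi - lo) / pp_norm[lab]
    clean <- lo + scale_deg * reconstruct(mk, t_local)
    d_clean <- scale_deg * derivative_model_eval(mk, t_local)
    if (config$extra_harmonic_frac > 0) {
      a_extra <- config$extra_harmonic_frac * scale_deg * m$amplitudes[1]
      ph <- stats::runif(5, 0, 2 * pi)
      for (j in seq_along(6:10)) {
        n_h <- (6:10)[j]
        arg <- 2 * pi * n_h * f0 * t_local + ph[j]
        clean <- clean + a_extra * cos(arg)
        d_clean <- d_clean - a_extra * 2 * pi * n_h * f0 * sin(arg)
      }
    }
    angle <- c(angle, clean)
    gyro <- c(gyro, d_clean)
  }
  # closing boundary minimum so the last stride is delimited
  last <- aligned[[labels[config$n_strides]]]
  angle <- c(angle, lo + (hi - lo) / pp_norm[labels[config$n_strides]] *
               reconstruct(last, 0))
  gyro <- c(gyro, (hi - lo) / pp_norm[labels[config$n_strides]] *
              derivative_model_eval(last, 0))

  if (config$noise_deg_sd > 0) {
    angle <- angle + stats::rnorm(length(angle), 0, config$noise_deg_sd)
  }
  if (config$gyro_noise_dps_sd > 0) {
    gyro <- gyro + stats::rnorm(length(gyro), 0, config$gyro_noise_dps_sd)
  }
  times <- (seq_along(angle) - 1L) / rate
  boundaries <- c(0, cumsum(stride_times))
  structure(
    list(angle = thigh_angle_series(times, angle, source = "direct"),
         gyro_dps = gyro,
         times_s = times,
         labels = labels,
         boundaries_s = boundaries,
         f0_hz = 1 / stride_times,
         stride_samples = stride_len,
         config = config),
    class = "gait_trial"
  )
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %d strides (%0.1f s), patterns {%s}\n",
              length(x$labels), max(x$times_s),
              paste(sort(unique(x$labels)), collapse = ",")))
  invisible(x)
}

#' Ground-truth strides of a simulated trial
#'
#' Crops the trial at its known stride boundaries (no detection involved),
#' returning the same [stride()] objects segmentation would ideally produce,
#' including all boundary strides.
#'
#' @param trial a `gait_trial` from [simulate_trial()].
#' @return List of [stride()] objects, one per simulated stride.
#' @export
trial_true_strides <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  starts <- cumsum(c(0L, trial$stride_samples))
  lapply(seq_along(trial$labels), function(k) {
    idx <- (starts[k] + 1L):starts[k + 1L]
    stride(angle_deg = trial$angle$angle_deg[idx],
           gyro_dps = trial$gyro_dps[idx],
           start_s = trial$boundaries_s[k],
           end_s = trial$boundaries_s[k + 1L],
           rate_hz = trial$config$rate_hz,
           index_in_trial = k)
  })
}

#' Simulate a raw 6-axis IMU stream from an angle trajectory
#'
#' Inverse of the orientation filter: the sagittal (y) gyro channel is the
#' differentiated angle plus bias and white noise, and the accelerometer
#' reads the gravity vector rotated by the angle in the sagittal plane
#' (`ax = sin(theta)`, `az = cos(theta)`, in g) plus white noise, so
#' quasi-static instants carry the correct inclination.
#'
#' @param angle a [thigh_angle_series()] (or a `gait_trial`, whose angle
#'   series is used).
#' @param config a [gait_sim_config()] supplying noise levels, bias and rate.
#' @param seed optional RNG seed.
#' @return An [imu_record()].
#' @export
simulate_imu <- function(angle, config = gait_sim_config(), seed = NULL) {
  if (inherits(angle, "gait_trial")) angle <- angle$angle
  stopifnot(inherits(angle, "thigh_angle_series"))
  if (!is.null(seed)) set.seed(seed)
  t <- angle$times_s
  th <- angle$angle_deg
  L <- length(t)
  dt <- diff(t)
  omega <- c((th[2] - th[1]) / dt[1],
             (th[3:L] - th[1:(L - 2)]) / (t[3:L] - t[1:(L - 2)]),
             (th[L] - th[L - 1]) / dt[L - 1])
  omega <- omega + config$gyro_bias_dps
  if (config$gyro_noise_dps_sd > 0) {
    omega <- omega + stats::rnorm(L, 0, config$gyro_noise_dps_sd)
  }
  rad <- th * pi / 180
  accel <- cbind(sin(rad), 0, cos(rad))
  if (config$accel_noise_g_sd > 0) {
    accel <- accel + matrix(stats::rnorm(3L * L, 0, config$accel_noise_g_sd), L, 3L)
  }
  imu_record(t, accel, cbind(0, omega, 0), rate_hz = config$rate_hz)
}
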