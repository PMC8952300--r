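#' Raw 6-axis IMU recording
#'
#' Container for a thigh-mounted IMU stream: 3-axis accelerometer in g and
#' 3-axis gyro in degrees per second, nominally at 100 Hz. Axis convention:
#' with the thigh vertical, z points along the thigh (so the static
#' accelerometer reads (0, 0, 1) g), x points anteriorly in the sagittal
#' plane, and y is the sagittal (mediolateral) rotation axis, so thigh
#' flexion produces a positive y gyro rate.
#'
#' @param times_s strictly increasing sample times in seconds.
#' @param accel_g numeric matrix L x 3 (columns ax, ay, az) in g.
#' @param gyro_dps numeric matrix L x 3 (columns gx, gy, gz) in deg/s.
#' @param rate_hz nominal sampling rate (default 100).
#' @return An `imu_record` object.
#' @export
imu_record <- function(times_s, accel_g, gyro_dps, rate_hz = 100) {
  times_s <- as.numeric(times_s)
  accel_g <- as.matrix(accel_g)
  gyro_dps <- as.matrix(gyro_dps)
  L <- length(times_s)
  if (L < 2L) stop("IMU record needs at least 2 samples", call. = FALSE)
  if (any(diff(times_s) <= 0)) {
    stop("non-monotone time: `times_s` must be strictly increasing",
         call. = FALSE)
  }
  if (nrow(accel_g) != L || nrow(gyro_dps) != L ||
      ncol(accel_g) != 3L || ncol(gyro_dps) != 3L) {
    stop("`accel_g` and `gyro_dps` must be L x 3 with L = length(times_s)",
         call. = FALSE)
  }
  med_dt <- stats::median(diff(times_s))
  if (abs(med_dt - 1 / rate_hz) > 0.05 / rate_hz) {
    stop(sprintf("median sample interval %.4g s deviates more than 5%% from 1/rate (%.4g s)",
                 med_dt, 1 / rate_hz), call. = FALSE)
  }
  dimnames(accel_g) <- NULL
  dimnames(gyro_dps) <- NULL
  structure(list(times_s = times_s, accel_g = accel_g, gyro_dps = gyro_dps,
                 rate_hz = rate_hz),
            class = "imu_record")
}

#' @export
print.imu_record <- function(x, ...) {
  cat(sprintf("<imu_record> %d samples @ %g Hz (%.2f s)\n",
              length(x$times_s), x$rate_hz,
              x$times_s[length(x$times_s)] - x$times_s[1]))
  invisible(x)
}

#' Thigh flexion-extension angle series
#'
#' @param times_s sample times in seconds.
#' @param angle_deg thigh angle in degrees, flexion positive.
#' @param source `"giof"` (estimated from IMU) or `"direct"` (given).
#' @return A `thigh_angle_series` object.
#' @export
thigh_angle_series <- function(times_s, angle_deg,
                               source = c("giof", "direct")) {
  source <- match.arg(source)
  times_s <- as.numeric(times_s)
  angle_deg <- as.numeric(angle_deg)
  if (length(times_s) != length(angle_deg)) {
    stop("`times_s` and `angle_deg` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(angle_deg))) {
    stop("angle series contains non-finite values", call. = FALSE)
  }
  structure(list(times_s = times_s, angle_deg = angle_deg, source = source),
            class = "thigh_angle_series")
}

#' @export
print.thigh_angle_series <- function(x, ...) {
  cat(sprintf("<thigh_angle_series> %d samples, range [%.1f, %.1f] deg, source %s\n",
              length(x$times_s), min(x$angle_deg), max(x$angle_deg), x$source))
  invisible(x)
}

#' Configuration for the gyro-integration orientation filter
#'
#' The filter integrates the sagittal gyro channel and, at quasi-static
#' instants (accelerometer magnitude close to 1 g, i.e. no body
#' acceleration), blends the integrated angle toward the inclination angle
#' implied by the gravity direction, which bounds the integration drift.
#'
#' @param sagittal_axis gyro column carrying the flexion-extension rate
#'   (1 = x, 2 = y, 3 = z; default 2).
#' @param alpha complementary blend weight applied per quasi-static sample
#'   (default 0.02).
#' @param quasi_static_tol tolerance on `| ||accel|| - 1 g |` for a sample to
#'   count as quasi-static, in g (default 0.05).
#' @return A `giof_config` list.
#' @export
giof_config <- function(sagittal_axis = 2L, alpha = 0.02,
                        quasi_static_tol = 0.05) {
  if (!sagittal_axis %in% 1:3) stop("`sagittal_axis` must be 1, 2 or 3", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (quasi_static_tol < 0) stop("`quasi_static_tol` must be >= 0", call. = FALSE)
  structure(list(sagittal_axis = as.integer(sagittal_axis), alpha = alpha,
                 quasi_static_tol = quasi_static_tol),
            class = "giof_config")
}

#' Estimate the thigh flexion-extension angle from raw IMU data
#'
#' Single-axis orientation estimation: the sagittal gyro rate is integrated
#' trapezoidally; whenever the accelerometer magnitude is within
#' `quasi_static_tol` of 1 g the running angle is blended toward the
#' accelerometer inclination `atan2(ax, az)` with weight `alpha`, which
#' keeps the gyro-bias drift bounded. The initial angle is taken from the
#' first quasi-static accelerometer reading (0 if none).
#'
#' @param imu an [imu_record()].
#' @param config a [giof_config()].
#' @return A [thigh_angle_series()] in degrees (source `"giof"`).
#' @export
estimate_thigh_angle <- function(imu, config = giof_config()) {
  stopifnot(inherits(imu, "imu_record"), inherits(config, "giof_config"))
  t <- imu$times_s
  omega <- imu$gyro_dps[, config$sagittal_axis]
  acc <- imu$accel_g
  L <- length(t)
  acc_norm <- sqrt(rowSums(acc^2))
  quasi_static <- abs(acc_norm - 1) <= config$quasi_static_tol
  theta_acc <- atan2(acc[, 1], acc[, 3]) * 180 / pi
  theta <- numeric(L)
  theta[1] <- if (quasi_static[1]) theta_acc[1] else 0
  a <- config$alpha
  dt <- diff(t)
  for (k in 2:L) {
    th <- theta[k - 1] + 0.5 * (omega[k] + omega[k - 1]) * dt[k - 1]
    if (a > 0 && quasi_static[k]) th <- (1 - a) * th + a * theta_acc[k]
    theta[k] <- th
  }
  thigh_angle_series(t, theta, source = "giof")
}
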