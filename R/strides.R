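#' One cropped stride
#'
#' A stride is the thigh-angle segment between two consecutive angle minima
#' (toe-off to toe-off), optionally carrying the paired gyro segment.
#'
#' @param angle_deg numeric vector of angle samples over the stride.
#' @param gyro_dps optional paired gyro samples (same length).
#' @param start_s,end_s stride boundaries in trial time, seconds.
#' @param rate_hz sampling rate.
#' @param index_in_trial position of the stride within the trial.
#' @return A `stride` object; `stride_time_s = end_s - start_s`.
#' @export
stride <- function(angle_deg, gyro_dps = NULL, start_s, end_s, rate_hz,
                   index_in_trial = NA_integer_) {
  angle_deg <- as.numeric(angle_deg)
  if (end_s <= start_s) stop("`end_s` must exceed `start_s`", call. = FALSE)
  if (!is.null(gyro_dps) && length(gyro_dps) != length(angle_deg)) {
    stop("paired gyro segment must match the angle segment length", call. = FALSE)
  }
  structure(list(angle_deg = angle_deg,
                 gyro_dps = if (is.null(gyro_dps)) NULL else as.numeric(gyro_dps),
                 start_s = start_s, end_s = end_s,
                 stride_time_s = end_s - start_s,
                 rate_hz = rate_hz,
                 index_in_trial = as.integer(index_in_trial)),
            class = "stride")
}

#' @export
print.stride <- function(x, ...) {
  cat(sprintf("<stride> #%d: %.3f s (%d samples), angle [%.1f, %.1f] deg%s\n",
              x$index_in_trial, x$stride_time_s, length(x$angle_deg),
              min(x$angle_deg), max(x$angle_deg),
              if (is.null(x$gyro_dps)) "" else ", paired gyro"))
  invisible(x)
}

#' Segment a walking trial into strides at thigh-angle minima
#'
#' Minima of the thigh-angle waveform mark toe-off; each stride is cropped
#' from one minimum to the next, and the first and last strides of the walk
#' are excluded as gait-initiation/termination transients. Minima are
#' detected with a prominence threshold (to keep the secondary
#' loading-response oscillation of the stronger stride patterns from
#' splitting strides) and a minimum separation.
#'
#' @param angle a [thigh_angle_series()].
#' @param gyro optional numeric vector of the sagittal gyro channel, same
#'   length as the angle series; carried into the strides when given.
#' @param min_prominence_frac minimum prominence of an accepted minimum as a
#'   fraction of the trial's amplitude range (default 0.2).
#' @param min_separation_s minimum spacing between detected minima in
#'   seconds (default 0.4).
#' @return List of [stride()] objects (may be empty when only two strides
#'   exist, since both are boundary strides).
#' @export
segment_strides <- function(angle, gyro = NULL,
                            min_prominence_frac = 0.2,
                            min_separation_s = 0.4) {
  stopifnot(inherits(angle, "thigh_angle_series"))
  x <- angle$angle_deg
  t <- angle$times_s
  if (!is.null(gyro) && length(gyro) != length(x)) {
    stop("`gyro` must match the angle series length", call. = FALSE)
  }
  rng <- diff(range(x))
  if (rng <= 0) stop("insufficient strides: fewer than 3 minima detected", call. = FALSE)
  rate <- 1 / stats::median(diff(t))
  minima <- detect_minima(x,
                          min_prominence = min_prominence_frac * rng,
                          min_separation = max(1L, round(min_separation_s * rate)))
  if (length(minima) < 3L) {
    stop("insufficient strides: fewer than 3 minima detected", call. = FALSE)
  }
  out <- list()
  # strides are half-open [min_k, min_{k+1}); drop the first and last
  for (k in seq_len(length(minima) - 1L)) {
    if (k == 1L || k == length(minima) - 1L) next
    i0 <- minima[k]; i1 <- minima[k + 1L]
    out[[length(out) + 1L]] <- stride(
      angle_deg = x[i0:(i1 - 1L)],
      gyro_dps = if (is.null(gyro)) NULL else gyro[i0:(i1 - 1L)],
      start_s = t[i0], end_s = t[i1], rate_hz = rate,
      index_in_trial = length(out) + 1L
    )
  }
  out
}

#' Toe-off time from a gyro segment
#'
#' Toe-off is the instant the sagittal gyro signal crosses zero with a
#' positive gradient. The crossing time is linearly interpolated between
#' the bracketing samples; the gradient is checked by central difference.
#'
#' @param gyro_segment numeric gyro samples in deg/s.
#' @param times sample times in seconds, same length.
#' @return Interpolated crossing time in seconds.
#' @export
detect_toe_off <- function(gyro_segment, times) {
  g <- as.numeric(gyro_segment)
  t <- as.numeric(times)
  if (length(g) != length(t) || length(g) < 3L) {
    stop("gyro segment and times must have equal length >= 3", call. = FALSE)
  }
  L <- length(g)
  grad <- c(g[2] - g[1], (g[3:L] - g[1:(L - 2)]) / 2, g[L] - g[L - 1])
  for (k in seq_len(L - 1L)) {
    crosses <- (g[k] < 0 && g[k + 1] >= 0) || (g[k] == 0 && g[k + 1] > 0)
    if (crosses && (grad[k] > 0 || grad[k + 1] > 0)) {
      if (g[k + 1] == g[k]) return(t[k])
      return(t[k] - g[k] * (t[k + 1] - t[k]) / (g[k + 1] - g[k]))
    }
  }
  stop("toe-off not found: no positive-gradient zero crossing", call. = FALSE)
}

#' Stride frequency from stride time
#'
#' The fundamental frequency of the stride's harmonic model is the
#' reciprocal of the stride time, an estimator that tracks the FFT
#' fundamental very closely.
#'
#' @param stride_time_s stride duration in seconds (> 0).
#' @return Fundamental frequency in Hz.
#' @export
stride_frequency_from_time <- function(stride_time_s) {
  if (!is.numeric(stride_time_s) || any(stride_time_s <= 0)) {
    stop("`stride_time_s` must be > 0", call. = FALSE)
  }
  1 / stride_time_s
}

#' Cascade a stride before the FFT
#'
#' Repeats the stride samples end-to-end to lengthen the record and refine
#' the FFT bin spacing (default 4 copies).
#'
#' @param stride_samples numeric vector.
#' @param copies number of copies >= 1.
#' @return Vector of length `copies * length(stride_samples)`.
#' @export
cascade_for_fft <- function(stride_samples, copies = 4) {
  if (copies < 1) stop("`copies` must be >= 1", call. = FALSE)
  if (length(stride_samples) == 0L) stop("empty stride", call. = FALSE)
  rep(as.numeric(stride_samples), as.integer(copies))
}

#' Normalize a stride in time and amplitude
#'
#' Resamples the stride to `n_points` samples by linear interpolation on
#' normalized time (stride time mapped to 1 s, half-open interval) and
#' rescales the amplitude to \[0, 1\].
#'
#' @param strd a [stride()] or a plain numeric vector of stride samples.
#' @param n_points output length (default 2000).
#' @param channel `"angle"` or `"gyro"` (which channel of a [stride()] to use).
#' @return A `normalized_stride`: list with `samples` (length `n_points`,
#'   min 0, max 1) and `original_range` (pre-normalization min and max).
#' @export
normalize_stride <- function(strd, n_points = 2000L,
                             channel = c("angle", "gyro")) {
  channel <- match.arg(channel)
  y <- if (inherits(strd, "stride")) {
    if (channel == "angle") strd$angle_deg else strd$gyro_dps
  } else {
    as.numeric(strd)
  }
  if (is.null(y)) stop("stride has no gyro channel", call. = FALSE)
  if (length(y) < 2L) stop("stride too short to resample", call. = FALSE)
  # half-open stride: sample L+1 would be the next stride's first sample
  u_in <- (seq_along(y) - 1L) / length(y)
  u_out <- (seq_len(n_points) - 1L) / n_points
  res <- stats::approx(u_in, y, xout = u_out, rule = 2)$y
  nrm <- normalize_to_unit_range(res)
  structure(list(samples = nrm$normalized,
                 original_range = c(nrm$offset, nrm$offset + nrm$scale)),
            class = "normalized_stride")
}

#' @export
print.normalized_stride <- function(x, ...) {
  cat(sprintf("<normalized_stride> %d samples, original range [%.2f, %.2f]\n",
              length(x$samples), x$original_range[1], x$original_range[2]))
  invisible(x)
}

#' Group normalized strides by nearest template under an RMSE cutoff
#'
#' A stride joins the group of the template with the lowest RMSE, provided
#' that RMSE (on the \[0, 1\] normalized amplitude scale) is below the
#' cutoff; strides matching no template stay unassigned.
#'
#' @param strides list of `normalized_stride` (or numeric vectors).
#' @param templates list of templates, same sample count as the strides.
#' @param rmse_cutoff threshold on the normalized scale (default 0.025,
#'   i.e. 2.5 percent).
#' @return List with `assignment` (integer template index per stride, NA if
#'   unassigned), `rmse` (strides x templates matrix) and `groups` (list of
#'   stride indices per template).
#' @export
group_by_template <- function(strides, templates, rmse_cutoff = 0.025) {
  s <- lapply(strides, stride_samples)
  tm <- lapply(templates, stride_samples)
  if (length(s) == 0L || length(tm) == 0L) {
    stop("strides and templates must be non-empty", call. = FALSE)
  }
  if (length(unique(vapply(c(s, tm), length, integer(1)))) != 1L) {
    stop("all strides and templates must share one sample count", call. = FALSE)
  }
  rm <- matrix(NA_real_, length(s), length(tm))
  for (i in seq_along(s)) {
    for (j in seq_along(tm)) rm[i, j] <- rmse(s[[i]], tm[[j]])
  }
  assignment <- apply(rm, 1, function(r) {
    j <- which.min(r)
    # strict cutoff, but an exact copy always belongs to its template
    if (r[j] < rmse_cutoff || r[j] == 0) j else NA_integer_
  })
  groups <- lapply(seq_along(tm), function(j) which(assignment == j))
  list(assignment = as.integer(assignment), rmse = rm, groups = groups)
}

#' Mean waveform template of a stride group
#'
#' Sample-wise mean of the group's normalized strides, re-normalized to the
#' unit range so the result is again a valid template.
#'
#' @param group non-empty list of `normalized_stride` (or numeric vectors).
#' @return A `normalized_stride` holding the mean template.
#' @export
mean_template <- function(group) {
  if (length(group) == 0L) stop("empty stride group", call. = FALSE)
  s <- lapply(group, stride_samples)
  m <- rowMeans(do.call(cbind, s))
  nrm <- normalize_to_unit_range(m)
  structure(list(samples = nrm$normalized,
                 original_range = c(nrm$offset, nrm$offset + nrm$scale)),
            class = "normalized_stride")
}

# accept either a normalized_stride or a bare numeric vector
stride_samples <- function(x) {
  if (inherits(x, "normalized_stride")) x$samples else as.numeric(x)
}

# Prominence-filtered local minima (indices), including trial-edge minima.
# Prominence of a minimum: height of the lower of the two barriers that must
# be climbed to reach a deeper minimum on either side. A side with no deeper
# value before the signal edge counts as an open (infinite) barrier, so
# boundary minima near the start or end of a walk are not penalized; spurious
# edge minima this admits fall into the first/last segments, which the
# segmentation excludes anyway.
detect_minima <- function(x, min_prominence, min_separation = 1L) {
  L <- length(x)
  if (L < 3L) return(integer(0))
  d <- diff(x)
  cand <- which(d[-1] > 0 & d[-(L - 1L)] < 0) + 1L   # strict interior minima
  if (x[1] < x[2]) cand <- c(1L, cand)
  if (x[L] < x[L - 1L]) cand <- c(cand, L)
  if (length(cand) == 0L) return(integer(0))
  prominence <- vapply(cand, function(i) {
    left <- if (i > 1L) {
      lower <- which(x[seq_len(i - 1L)] < x[i])
      if (length(lower)) max(x[(max(lower) + 1L):(i - 1L)]) else Inf
    } else Inf
    right <- if (i < L) {
      lower <- which(x[(i + 1L):L] < x[i]) + i
      if (length(lower)) max(x[(i + 1L):(min(lower) - 1L)]) else Inf
    } else Inf
    min(left, right) - x[i]
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) < 2L || min_separation <= 1L) return(keep)
  # enforce separation: greedily keep deeper minima
  ord <- keep[order(x[keep])]
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(chosen - i) >= min_separation)) chosen <- c(chosen, i)
  }
  sort(chosen)
}
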