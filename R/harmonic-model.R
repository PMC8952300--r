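#' Harmonic model of a periodic gait signal
#'
#' A harmonic model represents one stride cycle of a periodic signal
#' (thigh flexion-extension angle or sagittal gyro rate) as a truncated
#' Fourier series
#' \deqn{y(t) = b + \sum_{n=1}^{N} a_n \cos(2\pi n f_0 t + \varphi_n)}
#' where \eqn{f_0} is the fundamental (stride) frequency, \eqn{a_n} and
#' \eqn{\varphi_n} the amplitude and initial phase of the n-th harmonic,
#' and \eqn{b} the DC offset.
#'
#' @param dc_offset DC term \eqn{b}, in signal units.
#' @param fundamental_hz fundamental frequency \eqn{f_0} in Hz; must be > 0.
#' @param amplitudes numeric vector of harmonic amplitudes \eqn{a_1 \dots a_N},
#'   all >= 0.
#' @param phases numeric vector of initial phases \eqn{\varphi_1 \dots \varphi_N}
#'   in radians (cosine convention); same length as `amplitudes`.
#' @param signal_kind one of `"thigh_angle_deg"`, `"gyro_dps"`, `"normalized"`.
#'   Library templates are `"normalized"` with \eqn{a_1 = 1}.
#' @param label optional integer pattern label (1-6 for library models).
#'
#' @return An object of class `harmonic_model`.
#' @seealso [reconstruct()], [load_model_library()], [extract_harmonics()]
#' @export
#' @examples
#' m <- harmonic_model(0, 1, amplitudes = 1, phases = 0)
#' reconstruct(m, time_grid(duration_s = 1, rate_hz = 8))
harmonic_model <- function(dc_offset, fundamental_hz, amplitudes, phases,
                           signal_kind = c("thigh_angle_deg", "gyro_dps",
                                           "normalized"),
                           label = NA_integer_) {
  signal_kind <- match.arg(signal_kind)
  if (!is.numeric(fundamental_hz) || length(fundamental_hz) != 1L ||
      !is.finite(fundamental_hz) || fundamental_hz <= 0) {
    stop("invalid harmonic model: `fundamental_hz` must be a single positive number",
         call. = FALSE)
  }
  amplitudes <- as.numeric(amplitudes)
  phases <- as.numeric(phases)
  if (length(amplitudes) == 0L) {
    stop("invalid harmonic model: at least one harmonic is required",
         call. = FALSE)
  }
  if (length(amplitudes) != length(phases)) {
    stop("invalid harmonic model: `amplitudes` and `phases` must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("invalid harmonic model: amplitudes must be finite and >= 0",
         call. = FALSE)
  }
  if (any(!is.finite(phases))) {
    stop("invalid harmonic model: phases must be finite", call. = FALSE)
  }
  structure(
    list(
      dc_offset = as.numeric(dc_offset),
      fundamental_hz = as.numeric(fundamental_hz),
      amplitudes = amplitudes,
      phases = phases,
      n_harmonics = length(amplitudes),
      signal_kind = signal_kind,
      label = as.integer(label)
    ),
    class = "harmonic_model"
  )
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat(sprintf("<harmonic_model> %s, f0 = %g Hz, N = %d, b = %g\n",
              x$signal_kind, x$fundamental_hz, x$n_harmonics, x$dc_offset))
  tab <- data.frame(n = seq_len(x$n_harmonics),
                    amplitude = x$amplitudes, phase_rad = x$phases)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Uniform sampling grid
#'
#' @param start_s start time in seconds.
#' @param duration_s duration in seconds (> 0).
#' @param rate_hz sampling rate in Hz (default 100, the IMU streaming rate).
#'
#' @return A `time_grid` object; `grid_times()` materializes the sample times.
#' @export
time_grid <- function(start_s = 0, duration_s, rate_hz = 100) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be > 0", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) {
    stop("`rate_hz` must be > 0", call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  if (n < 2) stop("grid must contain at least 2 samples", call. = FALSE)
  structure(list(start_s = start_s, duration_s = duration_s,
                 rate_hz = rate_hz, n = as.integer(n)),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid a `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$start_s + seq(0L, grid$n - 1L) / grid$rate_hz
}

#' Evaluate a harmonic model on a time grid
#'
#' Sums the DC term and the N cosine harmonics of the model at each grid
#' time, i.e. evaluates the truncated Fourier series the model encodes.
#'
#' @param model a [harmonic_model()].
#' @param grid a [time_grid()], or a numeric vector of times in seconds.
#' @return Numeric vector of signal values, one per grid sample.
#' @export
reconstruct <- function(model, grid) {
  stopifnot(inherits(model, "harmonic_model"))
  t <- if (inherits(grid, "time_grid")) grid_times(grid) else as.numeric(grid)
  n <- seq_len(model$n_harmonics)
  # outer(): times x harmonics phase matrix, summed over harmonics
  arg <- outer(2 * pi * model$fundamental_hz * t, n) +
    matrix(model$phases, nrow = length(t), ncol = model$n_harmonics,
           byrow = TRUE)
  model$dc_offset +
    as.numeric(cos(arg) %*% model$amplitudes)
}

#' Normalize a signal to the unit range \[0, 1\]
#'
#' Applies the amplitude normalization used when building stride templates:
#' the waveform is affinely mapped so its minimum is 0 and its maximum 1.
#'
#' @param signal numeric vector with at least 2 samples and `max > min`.
#' @return A list with `normalized`, `offset` (the original minimum) and
#'   `scale` (the original peak-to-peak range), so that
#'   `normalized * scale + offset` recovers the input exactly.
#' @export
normalize_to_unit_range <- function(signal) {
  signal <- as.numeric(signal)
  if (length(signal) < 2L) {
    stop("signal must contain at least 2 samples", call. = FALSE)
  }
  lo <- min(signal); hi <- max(signal)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("degenerate range: signal maximum must exceed its minimum",
         call. = FALSE)
  }
  list(normalized = (signal - lo) / (hi - lo), offset = lo, scale = hi - lo)
}

#' Rescale a normalized waveform to the amplitude range of a reference
#'
#' Affine amplitude mapping so the output's minimum and maximum equal the
#' reference's; used to match a model-generated template to the measured
#' peak-to-peak thigh-angle (or gyro) variation before computing
#' correlation and RMSE.
#'
#' @param normalized numeric vector (any affine scale).
#' @param reference numeric vector of equal length with `max > min`.
#' @return Numeric vector with the reference's extrema and the input's shape.
#' @export
rescale_to_reference <- function(normalized, reference) {
  normalized <- as.numeric(normalized)
  reference <- as.numeric(reference)
  if (length(normalized) != length(reference)) {
    stop("`normalized` and `reference` must have equal length", call. = FALSE)
  }
  rlo <- min(reference); rhi <- max(reference)
  if (!is.finite(rlo) || !is.finite(rhi) || rhi <= rlo) {
    stop("degenerate reference: maximum must exceed minimum", call. = FALSE)
  }
  nlo <- min(normalized); nhi <- max(normalized)
  if (nhi <= nlo) {
    stop("degenerate input: maximum must exceed minimum", call. = FALSE)
  }
  (normalized - nlo) / (nhi - nlo) * (rhi - rlo) + rlo
}

#' Load the bundled library of stride-pattern harmonic models
#'
#' The package ships coefficient files for the six most common level-walking
#' stride patterns: six thigh-angle models with 5 harmonics each and six
#' gyro-signal models with 9 harmonics each, amplitudes normalized to the
#' fundamental (`a_1 = 1`) and phases in radians. The DC term of a template
#' is resolved at materialization time so that the one-period minimum is 0
#' (matching the \[0, 1\] amplitude-normalization convention of the templates).
#'
#' @param path optional directory holding `thigh_models.json` and
#'   `gyro_models.json`; defaults to the package's bundled resources.
#' @return A `model_library`: list with `thigh_models`, `gyro_models`
#'   (each a list of six [harmonic_model()]s) and `labels`.
#' @export
load_model_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "gaitharmonics")
  }
  thigh <- read_model_json(file.path(path, "thigh_models.json"))
  gyro <- read_model_json(file.path(path, "gyro_models.json"))
  if (length(thigh) != 6L || length(gyro) != 6L) {
    stop("model library format error: expected 6 thigh and 6 gyro models",
         call. = FALSE)
  }
  structure(list(thigh_models = thigh, gyro_models = gyro,
                 labels = vapply(thigh, `[[`, integer(1), "label")),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat(sprintf("<model_library> %d thigh-angle models (N=%d), %d gyro models (N=%d)\n",
              length(x$thigh_models), x$thigh_models[[1]]$n_harmonics,
              length(x$gyro_models), x$gyro_models[[1]]$n_harmonics))
  invisible(x)
}

#' Materialize a library template waveform over one stride
#'
#' Reconstructs one period of a library model on a uniform grid, applies the
#' min-zero DC convention, circularly shifts the waveform so that sample 1
#' coincides with the toe-off event (the global minimum for a thigh-angle
#' template; the first positive-gradient zero crossing for a gyro template,
#' which marks the same instant), and normalizes the amplitude to \[0, 1\].
#' This matches the minimum-to-minimum cropping convention of measured
#' strides, so templates and strides need no further time alignment.
#'
#' @param model a library [harmonic_model()].
#' @param n_points samples per stride (default 2000, the template resolution).
#' @param channel `"angle"` (align at minimum) or `"gyro"` (align at the
#'   positive-gradient zero crossing of the raw waveform).
#' @return Numeric vector of `n_points` values in \[0, 1\].
#' @export
model_template <- function(model, n_points = 2000L,
                           channel = c("angle", "gyro")) {
  channel <- match.arg(channel)
  aligned <- aligned_harmonic_model(model, channel, n_grid = n_points)
  period <- 1 / model$fundamental_hz
  t <- seq(0, period, length.out = n_points + 1L)[-(n_points + 1L)]
  normalize_to_unit_range(reconstruct(aligned, t))$normalized
}

#' Toe-off-aligned copy of a library model
#'
#' Returns an analytically equivalent harmonic model whose time origin is
#' shifted to the toe-off event (waveform minimum for the angle channel,
#' upward zero crossing for the gyro channel), with the DC term set so the
#' one-period minimum is 0. Reconstructing this model from t = 0 directly
#' produces a stride in the minimum-to-minimum cropping convention.
#'
#' @param model a [harmonic_model()].
#' @param channel `"angle"` or `"gyro"` alignment rule.
#' @param n_grid grid resolution used to locate the alignment instant
#'   (default 2000 points per period).
#' @return A [harmonic_model()] with shifted phases and min-zero DC.
#' @export
aligned_harmonic_model <- function(model, channel = c("angle", "gyro"),
                                   n_grid = 2000L) {
  channel <- match.arg(channel)
  period <- 1 / model$fundamental_hz
  t <- seq(0, period, length.out = n_grid + 1L)[-(n_grid + 1L)]
  base <- harmonic_model(0, model$fundamental_hz, model$amplitudes,
                         model$phases, signal_kind = model$signal_kind,
                         label = model$label)
  y <- reconstruct(base, t)
  shift <- template_alignment_index(y, channel)
  t_shift <- (shift - 1L) * period / n_grid
  n <- seq_len(model$n_harmonics)
  phases <- (model$phases + 2 * pi * n * model$fundamental_hz * t_shift) %% (2 * pi)
  harmonic_model(-min(y), model$fundamental_hz, model$amplitudes, phases,
                 signal_kind = model$signal_kind, label = model$label)
}

# Index of the toe-off sample within one reconstructed period.
template_alignment_index <- function(y, channel) {
  if (channel == "angle") return(which.min(y))
  # gyro: upward zero crossing of the waveform about its own midline; strong
  # loading-response patterns cross upward more than once per period, so take
  # the crossing circularly nearest t = 0 (the phase convention of the
  # toe-off-cropped strides the models were fitted to)
  n <- length(y)
  y0 <- y - mean(y)
  nxt <- c(y0[-1], y0[1])
  idx <- which(y0 <= 0 & nxt > 0) %% n + 1L
  if (length(idx) == 0L) return(which.min(y))
  d <- pmin(idx - 1L, n - (idx - 1L))
  idx[which.min(d)]
}

# internal JSON reader shared with io module
read_model_json <- function(file) {
  if (!file.exists(file)) {
    stop(sprintf("model file not found: %s", file), call. = FALSE)
  }
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (!is.null(raw$harmonics)) raw <- list(raw)  # single-model file
  lapply(raw, function(m) {
    required <- c("signal_kind", "fundamental_hz", "dc_offset", "harmonics")
    if (!all(required %in% names(m))) {
      stop("model JSON format error: missing one of ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    ns <- vapply(m$harmonics, function(h) as.integer(h$n), integer(1))
    if (!identical(ns, seq_along(ns))) {
      stop("model JSON format error: harmonics must be consecutive n = 1, 2, ...",
           call. = FALSE)
    }
    harmonic_model(
      dc_offset = m$dc_offset,
      fundamental_hz = m$fundamental_hz,
      amplitudes = vapply(m$harmonics, function(h) as.numeric(h$amplitude),
                          numeric(1)),
      phases = vapply(m$harmonics, function(h) as.numeric(h$phase_rad),
                      numeric(1)),
      signal_kind = m$signal_kind,
      label = if (is.null(m$label)) NA_integer_ else m$label
    )
  })
}
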