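#' One-sided amplitude/phase spectrum of a sampled signal
#'
#' Computes the FFT with the transform length equal to the input length
#' (no zero padding to a power of two, so the bin spacing is exactly
#' `rate_hz / length(signal)`), and converts to a one-sided amplitude
#' spectrum calibrated so a pure cosine `A*cos(2*pi*f*t + phi)` sampled
#' over an integer number of periods yields amplitude `A` and phase `phi`
#' at the bin of `f`. The DC term is the signal mean.
#'
#' @param signal numeric vector with at least 8 samples.
#' @param rate_hz sampling rate in Hz.
#' @return A `spectrum_gait` object with fields `freqs_hz`, `amplitudes`,
#'   `phases_rad` (cosine convention, wrapped to `[0, 2*pi)`), `dc`,
#'   `n_input` and `rate_hz`.
#' @export
compute_spectrum <- function(signal, rate_hz) {
  signal <- as.numeric(signal)
  L <- length(signal)
  if (L < 8L) stop("signal too short: at least 8 samples required", call. = FALSE)
  if (any(!is.finite(signal))) stop("signal contains non-finite values", call. = FALSE)
  X <- stats::fft(signal)
  n_one_sided <- floor(L / 2)            # bins 1..floor(L/2), DC held separately
  k <- seq_len(n_one_sided)
  amplitudes <- 2 * Mod(X[k + 1L]) / L
  phases <- Arg(X[k + 1L]) %% (2 * pi)
  structure(
    list(freqs_hz = k * rate_hz / L,
         amplitudes = amplitudes,
         phases_rad = phases,
         dc = Re(X[1L]) / L,
         n_input = L,
         rate_hz = rate_hz),
    class = "spectrum_gait"
  )
}

#' @export
print.spectrum_gait <- function(x, ...) {
  cat(sprintf("<spectrum_gait> %d bins, df = %g Hz, dc = %g\n",
              length(x$freqs_hz), x$freqs_hz[1], x$dc))
  invisible(x)
}

#' Locate the fundamental frequency as the highest spectral peak
#'
#' The stride (fundamental) frequency carries the largest amplitude in the
#' spectrum of a walking trial, so the fundamental is simply the non-DC bin
#' of globally maximal amplitude. Ties break toward the lower frequency.
#'
#' @param spec a `spectrum_gait` from [compute_spectrum()].
#' @return List with `f0_hz` and `bin` (1-based index into the one-sided bins).
#' @export
find_fundamental <- function(spec) {
  stopifnot(inherits(spec, "spectrum_gait"))
  if (length(spec$amplitudes) < 2L) {
    stop("spectrum must contain at least 2 non-DC bins", call. = FALSE)
  }
  if (all(spec$amplitudes == 0)) {
    stop("no fundamental: spectrum has no non-zero amplitude", call. = FALSE)
  }
  bin <- which.max(spec$amplitudes)  # which.max returns the first (lowest-f) max
  list(f0_hz = spec$freqs_hz[bin], bin = as.integer(bin))
}

#' Extract amplitudes and phases of the first N harmonics
#'
#' For each harmonic number n the amplitude and phase are read at the local
#' amplitude maximum within one bin of the bin nearest `n * f0_hz`, which
#' tolerates a fundamental slightly off the FFT grid. The DC component is
#' carried over from the spectrum, so the result is directly usable as a
#' harmonic model.
#'
#' @param spec a `spectrum_gait`.
#' @param f0_hz fundamental frequency in Hz.
#' @param n_harmonics number of harmonics N >= 1; `n_harmonics * f0_hz` must
#'   lie below the Nyquist frequency.
#' @return A `harmonic_set`: list with `fundamental_hz`, `dc` and a data frame
#'   `entries` with columns `n`, `amplitude`, `phase_rad`.
#' @export
extract_harmonics <- function(spec, f0_hz, n_harmonics) {
  stopifnot(inherits(spec, "spectrum_gait"))
  if (n_harmonics < 1L) stop("`n_harmonics` must be >= 1", call. = FALSE)
  nyquist <- spec$rate_hz / 2
  if (n_harmonics * f0_hz >= nyquist) {
    stop(sprintf("harmonic %d at %.3g Hz is at or above Nyquist (%.3g Hz)",
                 n_harmonics, n_harmonics * f0_hz, nyquist), call. = FALSE)
  }
  df <- spec$freqs_hz[1]
  nbins <- length(spec$amplitudes)
  pick <- function(n) {
    centre <- round(n * f0_hz / df)
    cand <- max(1L, centre - 1L):min(nbins, centre + 1L)
    cand[which.max(spec$amplitudes[cand])]
  }
  bins <- vapply(seq_len(n_harmonics), pick, integer(1))
  structure(
    list(fundamental_hz = f0_hz,
         dc = spec$dc,
         entries = data.frame(n = seq_len(n_harmonics),
                              amplitude = spec$amplitudes[bins],
                              phase_rad = spec$phases_rad[bins])),
    class = "harmonic_set"
  )
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat(sprintf("<harmonic_set> f0 = %g Hz, dc = %g\n", x$fundamental_hz, x$dc))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Convert an extracted harmonic set into a harmonic model
#'
#' @param hset a `harmonic_set` from [extract_harmonics()].
#' @param signal_kind passed to [harmonic_model()].
#' @return A [harmonic_model()] with the set's DC, amplitudes and phases.
#' @export
as_harmonic_model <- function(hset, signal_kind = "thigh_angle_deg") {
  stopifnot(inherits(hset, "harmonic_set"))
  harmonic_model(hset$dc, hset$fundamental_hz,
                 hset$entries$amplitude, hset$entries$phase_rad,
                 signal_kind = signal_kind)
}

#' Number of significant harmonics under the 1 percent median rule
#'
#' A harmonic is significant while the median (over strides) of its
#' fundamental-normalized amplitude stays at or above the cutoff. The count
#' is the largest N such that every harmonic up to N passes; the
#' fundamental is always significant.
#'
#' @param normalized_amplitude_rows numeric matrix (or data frame) with one
#'   row per stride and column n holding `a_n / a_1` (so column 1 is all 1).
#' @param cutoff_fraction significance cutoff as a fraction of the
#'   fundamental amplitude (default 0.01).
#' @return Integer count of significant harmonics, >= 1.
#' @export
significant_harmonic_count <- function(normalized_amplitude_rows,
                                       cutoff_fraction = 0.01) {
  m <- as.matrix(normalized_amplitude_rows)
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("at least one row of normalized amplitudes is required", call. = FALSE)
  }
  med <- apply(m, 2, stats::median)
  below <- which(med < cutoff_fraction)
  if (length(below) == 0L) return(ncol(m))
  max(1L, min(below) - 1L)
}

#' Fit a harmonic model to one stride by cascaded FFT
#'
#' Implements the per-stride spectral pipeline: the stride samples are
#' cascaded (repeated end-to-end, default 4 copies) to lengthen the record
#' and refine the FFT bin spacing, the spectrum is computed with transform
#' length equal to the cascaded length, and the first `n_harmonics`
#' harmonics are extracted at the stride frequency. When `f0_hz` is omitted
#' it is taken from the stride time (`1 / stride_time`), the estimator shown
#' to track the FFT fundamental closely.
#'
#' @param stride_samples numeric vector, one cropped stride.
#' @param rate_hz sampling rate in Hz.
#' @param n_harmonics harmonics to keep (5 for thigh angle, 9 for gyro).
#' @param f0_hz optional fundamental; default `rate_hz / length(stride_samples)`.
#' @param cascade_copies copies used for the cascaded FFT (default 4).
#' @param signal_kind passed to the returned model.
#' @return A [harmonic_model()].
#' @export
fit_stride_model <- function(stride_samples, rate_hz, n_harmonics = 5,
                             f0_hz = NULL, cascade_copies = 4,
                             signal_kind = "thigh_angle_deg") {
  stride_samples <- as.numeric(stride_samples)
  if (is.null(f0_hz)) f0_hz <- rate_hz / length(stride_samples)
  cascaded <- cascade_for_fft(stride_samples, cascade_copies)
  spec <- compute_spectrum(cascaded, rate_hz)
  as_harmonic_model(extract_harmonics(spec, f0_hz, n_harmonics),
                    signal_kind = signal_kind)
}
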