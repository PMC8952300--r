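#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] used as the waveform
#' similarity metric throughout the stride classification pipeline.
#'
#' @param x,y equal-length numeric vectors, both non-constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("inputs must have length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Root-mean-square error between two waveforms
#'
#' @param x,y equal-length numeric vectors.
#' @return `sqrt(mean((x - y)^2))`, in the units of the inputs.
#' @export
rmse <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("inputs must be non-empty", call. = FALSE)
  sqrt(mean((x - y)^2))
}

# Library-model waveform on a stride grid of L samples: the 2000-point
# aligned template linearly resampled to the stride's own grid.
model_stride_waveform <- function(model, n_samples, channel = "angle",
                                  template_points = 2000L) {
  tpl <- model_template(model, n_points = template_points, channel = channel)
  u_in <- (seq_len(template_points) - 1L) / template_points
  u_out <- (seq_len(n_samples) - 1L) / n_samples
  stats::approx(u_in, tpl, xout = u_out, rule = 2)$y
}

#' Classify strides against the six stride-pattern models
#'
#' For each stride and each library model, the model waveform is generated
#' at the stride's fundamental frequency on the stride's own sampling grid,
#' rescaled to the stride's measured amplitude range, and compared with the
#' measured waveform by Pearson correlation and RMSE. The best-matching
#' model for a stride is the one with the highest correlation (ties break
#' toward the lower model index); a flag records strides whose lowest-RMSE
#' model disagrees with the correlation choice.
#'
#' @param strides non-empty list of [stride()] objects.
#' @param library a `model_library` from [load_model_library()].
#' @param channel `"angle"` (thigh angle vs. the thigh models) or `"gyro"`
#'   (paired gyro segments vs. the gyro models).
#' @return A `classification_matrix`: `correlations` and `rmses`
#'   (strides x models), `best_model`, `best_model_rmse`, `disagreement`,
#'   `stride_labels`, `model_labels`, `channel`.
#' @export
classify_strides <- function(strides, library, channel = c("angle", "gyro")) {
  channel <- match.arg(channel)
  stopifnot(inherits(library, "model_library"))
  if (length(strides) == 0L) stop("no strides to classify", call. = FALSE)
  models <- if (channel == "angle") library$thigh_models else library$gyro_models
  n_s <- length(strides); n_m <- length(models)
  correlations <- matrix(NA_real_, n_s, n_m)
  rmses <- matrix(NA_real_, n_s, n_m)
  for (i in seq_len(n_s)) {
    strd <- strides[[i]]
    y <- if (channel == "angle") strd$angle_deg else strd$gyro_dps
    if (is.null(y)) stop("stride has no gyro channel", call. = FALSE)
    for (j in seq_len(n_m)) {
      w <- model_stride_waveform(models[[j]], length(y), channel = channel)
      w <- rescale_to_reference(w, y)
      correlations[i, j] <- pearson_correlation(w, y)
      rmses[i, j] <- rmse(w, y)
    }
  }
  best_model <- apply(correlations, 1, which.max)    # first max = lower index
  best_model_rmse <- apply(rmses, 1, which.min)
  structure(
    list(correlations = correlations,
         rmses = rmses,
         best_model = as.integer(best_model),
         best_model_rmse = as.integer(best_model_rmse),
         disagreement = best_model != best_model_rmse,
         stride_labels = vapply(strides, function(s) s$index_in_trial, integer(1)),
         model_labels = library$labels,
         channel = channel),
    class = "classification_matrix"
  )
}

#' @export
print.classification_matrix <- function(x, ...) {
  cat(sprintf("<classification_matrix> %d strides x %d models (%s channel)\n",
              nrow(x$correlations), ncol(x$correlations), x$channel))
  cat("best model per stride:", paste(x$best_model, collapse = " "), "\n")
  if (any(x$disagreement)) {
    cat("correlation/RMSE disagreement on strides:",
        paste(which(x$disagreement), collapse = " "), "\n")
  }
  invisible(x)
}

#' Predict a full trial from a single stride's harmonic model
#'
#' Reconstructs every stride of a trial from one harmonic model (typically
#' extracted from the first stride): for each stride the fundamental
#' frequency is re-estimated from that stride's time, the model is
#' evaluated on the stride's grid, and the amplitude is rescaled to the
#' stride's measured range. The per-stride reconstructions are concatenated
#' and compared with the measured series.
#'
#' @param trial_strides non-empty list of [stride()] objects.
#' @param model a [harmonic_model()] (e.g. from [fit_stride_model()] on the
#'   first stride).
#' @param rescale `"peak_to_peak"` (default; match the stride's measured
#'   min/max) or `"max_as_a1"` (scale the harmonics so the fundamental
#'   amplitude equals the stride's maximum thigh angle).
#' @return List with `predicted_deg`, `measured_deg`, `per_stride` (data
#'   frame of correlation and RMSE per stride), `correlation` and
#'   `rmse_deg` over the concatenated trial, and `skipped` (indices of
#'   degenerate strides left out).
#' @export
predict_trial <- function(trial_strides, model,
                          rescale = c("peak_to_peak", "max_as_a1")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(model, "harmonic_model"))
  if (length(trial_strides) == 0L) stop("no strides to predict", call. = FALSE)
  predicted <- numeric(0)
  measured <- numeric(0)
  per <- list()
  skipped <- integer(0)
  for (i in seq_along(trial_strides)) {
    strd <- trial_strides[[i]]
    y <- strd$angle_deg
    f0 <- stride_frequency_from_time(strd$stride_time_s)
    m_i <- harmonic_model(model$dc_offset, f0, model$amplitudes, model$phases,
                          signal_kind = model$signal_kind)
    t_local <- (seq_along(y) - 1L) / strd$rate_hz
    yhat <- reconstruct(m_i, t_local)
    yhat <- tryCatch(
      if (rescale == "peak_to_peak") {
        rescale_to_reference(yhat, y)
      } else {
        s <- max(y) / model$amplitudes[1]
        model$dc_offset + (yhat - model$dc_offset) * s
      },
      error = function(e) NULL
    )
    if (is.null(yhat)) {
      message(sprintf("predict_trial: stride %d skipped (degenerate range)", i))
      skipped <- c(skipped, i)
      next
    }
    per[[length(per) + 1L]] <- data.frame(
      stride = i,
      correlation = pearson_correlation(yhat, y),
      rmse_deg = rmse(yhat, y)
    )
    predicted <- c(predicted, yhat)
    measured <- c(measured, y)
  }
  if (length(predicted) == 0L) stop("all strides degenerate", call. = FALSE)
  list(predicted_deg = predicted,
       measured_deg = measured,
       per_stride = do.call(rbind, per),
       correlation = pearson_correlation(predicted, measured),
       rmse_deg = rmse(predicted, measured),
       skipped = skipped)
}
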