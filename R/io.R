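#' Pipeline configuration with the study's default parameter values
#'
#' Central knob set for the analysis pipeline. Defaults: 100 Hz sampling,
#' 2000-point stride resampling, 5 significant harmonics for thigh angle
#' and 9 for the gyro signal, 1 percent median significance cutoff,
#' 2.5 percent template RMSE cutoff, and 4-fold stride cascading before
#' the per-stride FFT.
#'
#' @param sampling_rate_hz IMU sampling rate.
#' @param resample_points samples per normalized stride.
#' @param n_harmonics_angle harmonics kept for thigh-angle models.
#' @param n_harmonics_gyro harmonics kept for gyro models.
#' @param significance_cutoff median-amplitude significance cutoff
#'   (fraction of the fundamental).
#' @param template_rmse_cutoff stride-to-template grouping cutoff on the
#'   normalized scale.
#' @param cascade_copies stride copies for the cascaded FFT.
#' @param orientation a [giof_config()].
#' @param simulation a [gait_sim_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sampling_rate_hz = 100,
                            resample_points = 2000L,
                            n_harmonics_angle = 5L,
                            n_harmonics_gyro = 9L,
                            significance_cutoff = 0.01,
                            template_rmse_cutoff = 0.025,
                            cascade_copies = 4L,
                            orientation = giof_config(),
                            simulation = gait_sim_config()) {
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 resample_points = as.integer(resample_points),
                 n_harmonics_angle = as.integer(n_harmonics_angle),
                 n_harmonics_gyro = as.integer(n_harmonics_gyro),
                 significance_cutoff = significance_cutoff,
                 template_rmse_cutoff = template_rmse_cutoff,
                 cascade_copies = as.integer(cascade_copies),
                 orientation = orientation,
                 simulation = simulation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys override [pipeline_config()] defaults; `orientation:` and
#' `simulation:` sub-maps override the corresponding sub-configs.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configs", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  ori <- do.call(giof_config, raw$orientation %||% list())
  sim <- do.call(gait_sim_config, raw$simulation %||% list())
  raw$orientation <- NULL; raw$simulation <- NULL
  do.call(pipeline_config, c(raw, list(orientation = ori, simulation = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

imu_csv_header <- c("time_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")

#' Read a raw IMU CSV file
#'
#' Expects the exact header `time_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps`,
#' one sample per row. Malformed or non-finite rows and non-monotone time
#' are rejected with the offending line number.
#'
#' @param path CSV file path.
#' @param rate_hz nominal sampling rate (default 100).
#' @return An [imu_record()].
#' @export
read_imu_csv <- function(path, rate_hz = 100) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(d), imu_csv_header)) {
    stop(sprintf("IMU CSV parse error: header must be `%s`",
                 paste(imu_csv_header, collapse = ",")), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(d) | !apply(d, 1, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop(sprintf("IMU CSV parse error: non-finite value at line %d", bad[1] + 1L),
         call. = FALSE)
  }
  if (any(diff(d$time_s) <= 0)) {
    stop(sprintf("IMU CSV parse error: non-monotone time at line %d",
                 which(diff(d$time_s) <= 0)[1] + 2L), call. = FALSE)
  }
  imu_record(d$time_s,
             as.matrix(d[, c("ax_g", "ay_g", "az_g")]),
             as.matrix(d[, c("gx_dps", "gy_dps", "gz_dps")]),
             rate_hz = rate_hz)
}

#' @rdname read_imu_csv
#' @param imu an [imu_record()].
#' @export
write_imu_csv <- function(imu, path) {
  stopifnot(inherits(imu, "imu_record"))
  d <- data.frame(imu$times_s, imu$accel_g, imu$gyro_dps)
  names(d) <- imu_csv_header
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a thigh-angle CSV (`time_s,angle_deg`)
#'
#' @param path CSV file path.
#' @return `read_angle_csv()`: a [thigh_angle_series()].
#' @export
read_angle_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(d), c("time_s", "angle_deg"))) {
    stop("angle CSV parse error: header must be `time_s,angle_deg`", call. = FALSE)
  }
  bad <- which(!is.finite(d$time_s) | !is.finite(d$angle_deg))
  if (length(bad)) {
    stop(sprintf("angle CSV parse error: non-finite value at line %d", bad[1] + 1L),
         call. = FALSE)
  }
  if (any(diff(d$time_s) <= 0)) {
    stop(sprintf("angle CSV parse error: non-monotone time at line %d",
                 which(diff(d$time_s) <= 0)[1] + 2L), call. = FALSE)
  }
  thigh_angle_series(d$time_s, d$angle_deg, source = "direct")
}

#' @rdname read_angle_csv
#' @param angle a [thigh_angle_series()].
#' @export
write_angle_csv <- function(angle, path) {
  stopifnot(inherits(angle, "thigh_angle_series"))
  utils::write.csv(data.frame(time_s = angle$times_s, angle_deg = angle$angle_deg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write harmonic models to JSON
#'
#' Serializes one model or a list of models in the package's model schema:
#' `signal_kind`, `fundamental_hz`, `dc_offset` and a `harmonics` array of
#' `{n, amplitude, phase_rad}` entries. [read_models_json()] is the inverse.
#'
#' @param models a [harmonic_model()] or list of them.
#' @param path output JSON path.
#' @export
write_models_json <- function(models, path) {
  if (inherits(models, "harmonic_model")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(label = if (is.na(m$label)) NULL else m$label,
         signal_kind = m$signal_kind,
         fundamental_hz = m$fundamental_hz,
         dc_offset = m$dc_offset,
         harmonics = lapply(seq_len(m$n_harmonics), function(n) {
           list(n = n, amplitude = m$amplitudes[n], phase_rad = m$phases[n])
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models_json
#' @return `read_models_json()`: a list of [harmonic_model()]s.
#' @export
read_models_json <- function(path) {
  read_model_json(path)
}

#' Export a classification matrix
#'
#' CSV layout follows the matrix-figure convention: one row per model, one
#' column per stride. Two files are written for `which = "both"`:
#' `<stem>_correlation.csv` and `<stem>_rmse.csv`. The JSON export carries
#' both matrices plus the per-stride best model and disagreement flags.
#'
#' @param cm a `classification_matrix` from [classify_strides()].
#' @param stem output path stem (CSV) or full path (JSON).
#' @export
write_classification_csv <- function(cm, stem) {
  stopifnot(inherits(cm, "classification_matrix"))
  fmt <- function(m) {
    out <- t(m)
    rownames(out) <- paste0("model_", cm$model_labels)
    colnames(out) <- paste0("stride_", seq_len(ncol(out)))
    out
  }
  utils::write.csv(fmt(cm$correlations), paste0(stem, "_correlation.csv"))
  utils::write.csv(fmt(cm$rmses), paste0(stem, "_rmse.csv"))
  invisible(stem)
}

#' @rdname write_classification_csv
#' @export
write_classification_json <- function(cm, stem) {
  stopifnot(inherits(cm, "classification_matrix"))
  jsonlite::write_json(
    list(channel = cm$channel,
         model_labels = cm$model_labels,
         correlations = cm$correlations,
         rmses = cm$rmses,
         best_model = cm$best_model,
         best_model_rmse = cm$best_model_rmse,
         disagreement = cm$disagreement),
    stem, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Export normalized strides or templates as CSV plus JSON sidecar
#'
#' The CSV holds one column per stride with `resample_points` rows of
#' normalized amplitude; the sidecar JSON records the timing metadata and
#' original amplitude ranges.
#'
#' @param strides list of `normalized_stride`.
#' @param meta optional list of [stride()] objects supplying timing metadata.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @export
write_strides_csv <- function(strides, stem, meta = NULL) {
  m <- do.call(cbind, lapply(strides, stride_samples))
  colnames(m) <- paste0("stride_", seq_len(ncol(m)))
  utils::write.csv(m, paste0(stem, ".csv"), row.names = FALSE)
  sidecar <- lapply(seq_along(strides), function(i) {
    out <- list(original_range = strides[[i]]$original_range)
    if (!is.null(meta)) {
      out$start_s <- meta[[i]]$start_s
      out$end_s <- meta[[i]]$end_s
      out$stride_time_s <- meta[[i]]$stride_time_s
    }
    out
  })
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Write the ground truth of a simulated trial as JSON
#'
#' @param trial a `gait_trial` from [simulate_trial()].
#' @param path output JSON path.
#' @export
write_ground_truth_json <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  jsonlite::write_json(list(labels = trial$labels,
                            boundaries_s = trial$boundaries_s,
                            f0_hz = trial$f0_hz),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}
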