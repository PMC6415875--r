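#' Fit an NDIR sensor calibration line
#'
#' Calibration against standard gases of known CO2 concentration (typically
#' 0, 100, 500 and 1000 ppm). The sensors respond linearly in this range, so
#' a least-squares line mapping the raw reading to the true concentration is
#' fitted directly: `true_ppm = slope * raw + intercept`.
#'
#' @param standards data frame with columns `true_ppm` and `raw_reading`
#'   (one row per standard-gas measurement); an optional `sensor_id` column
#'   is carried into the model.
#' @param sensor_id overrides the sensor id recorded in the model.
#' @return An object of class `calibration_model` with `slope`, `intercept`,
#'   `residual_sd`, `n_standards`, `sensor_id`.
#' @export
fit_calibration <- function(standards, sensor_id = NULL) {
  if (!all(c("true_ppm", "raw_reading") %in% names(standards))) {
    stop("standards needs columns true_ppm, raw_reading", call. = FALSE)
  }
  standards <- standards[complete.cases(
    standards[c("true_ppm", "raw_reading")]), , drop = FALSE]
  if (nrow(standards) < 2L) {
    stop("calibration needs at least 2 standards", call. = FALSE)
  }
  if (length(unique(standards$raw_reading)) < 2L) {
    stop("calibration standards have no spread in raw_reading", call. = FALSE)
  }
  fit <- lm(true_ppm ~ raw_reading, data = standards)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted calibration slope is not positive", call. = FALSE)
  }
  if (is.null(sensor_id)) {
    sensor_id <- if ("sensor_id" %in% names(standards))
      as.character(standards$sensor_id[1]) else "sensor"
  }
  structure(list(sensor_id = sensor_id,
                 slope = slope,
                 intercept = unname(coef(fit)[1]),
                 residual_sd = if (nrow(standards) > 2L)
                   suppressWarnings(summary(fit)$sigma) else 0,
                 n_standards = nrow(standards)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s: true = %.5g * raw + %.5g (n = %d, resid sd %.3g)\n",
    x$sensor_id, x$slope, x$intercept, x$n_standards, x$residual_sd))
  invisible(x)
}

#' Apply a calibration line to a raw trace
#'
#' @param trace an uncalibrated [sensor_trace()].
#' @param model a [fit_calibration()] model; its sensor id must match the
#'   trace's unless `force = TRUE`.
#' @param force apply even on a sensor-id mismatch or an already-calibrated
#'   trace.
#' @return The calibrated trace.
#' @export
apply_calibration <- function(trace, model, force = FALSE) {
  stopifnot(inherits(trace, "sensor_trace"),
            inherits(model, "calibration_model"))
  if (attr(trace, "calibrated") && !force) {
    stop("trace is already calibrated (use force = TRUE to recalibrate)",
         call. = FALSE)
  }
  if (!identical(attr(trace, "sensor_id"), model$sensor_id) && !force) {
    stop(sprintf("sensor id mismatch: trace '%s' vs model '%s'",
                 attr(trace, "sensor_id"), model$sensor_id), call. = FALSE)
  }
  trace_with(trace, co2_ppm = model$slope * trace$co2_ppm + model$intercept,
             calibrated = TRUE)
}

#' Average a trace over non-overlapping windows
#'
#' Raw 1-s readings are averaged over fixed windows (60 s by default) to
#' reduce NDIR noise. Windows are aligned to multiples of `window_s` from
#' time 0; the output timestamp is the window midpoint. Windows that span a
#' duty-cycle gap (i.e. contain samples from more than one segment) or are
#' covered less than `min_coverage` are dropped.
#'
#' @param trace a [sensor_trace()].
#' @param window_s window length in seconds (default 60); must be at least
#'   the sampling interval.
#' @param min_coverage minimum fraction of the window that must be sampled
#'   (default 0.5).
#' @return A [sensor_trace()] on the averaged grid.
#' @export
average_window <- function(trace, window_s = 60, min_coverage = 0.5) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  dt <- if (nrow(trace) > 1L) median(diff(trace$time_s)) else window_s
  if (window_s < dt) {
    stop("window_s must be at least the sampling interval", call. = FALSE)
  }
  win <- floor(trace$time_s / window_s)
  key <- factor(win, levels = unique(win))
  n <- as.integer(table(key))
  mean_ppm <- as.numeric(tapply(trace$co2_ppm, key, mean))
  nseg <- as.integer(tapply(trace$segment, key, function(s) length(unique(s))))
  keep <- nseg == 1L & (n * dt) >= min_coverage * window_s
  if (!any(keep)) stop("no complete averaging window in trace", call. = FALSE)
  mid <- (unique(win) + 0.5) * window_s
  # the averaged grid has its own time base; re-derive the gap threshold
  trace_with(trace, time_s = mid[keep], co2_ppm = mean_ppm[keep],
             gap_s = NULL)
}

#' Convert ppm (by volume) to molar concentration
#'
#' Ideal-gas conversion `c = ppm * 1e-6 * P / (R T)` in mol m-3. Defaults are
#' the growth-room conditions: 21 C (294.15 K) and standard pressure.
#'
#' @param ppm concentration in ppm by volume.
#' @param T_K temperature in kelvin.
#' @param P_Pa pressure in pascal.
#' @return Concentration in mol m-3.
#' @export
ppm_to_molar <- function(ppm, T_K = 294.15, P_Pa = 101325) {
  if (!is.finite(T_K) || T_K <= 0 || !is.finite(P_Pa) || P_Pa <= 0) {
    stop("T_K and P_Pa must be positive", call. = FALSE)
  }
  ppm * 1e-6 * P_Pa / (.R_GAS * T_K)
}

#' @rdname ppm_to_molar
#' @param molar concentration in mol m-3.
#' @export
molar_to_ppm <- function(molar, T_K = 294.15, P_Pa = 101325) {
  if (!is.finite(T_K) || T_K <= 0 || !is.finite(P_Pa) || P_Pa <= 0) {
    stop("T_K and P_Pa must be positive", call. = FALSE)
  }
  molar * 1e6 * .R_GAS * T_K / P_Pa
}
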