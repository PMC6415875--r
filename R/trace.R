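#' Construct a sensor trace
#'
#' A `sensor_trace` is the package's representation of one NDIR CO2 sensor
#' log: time in seconds since experiment start and CO2 concentration in ppm
#' by volume. Sensors are duty-cycled (switched off periodically to avoid
#' overheating), so a trace may contain gaps; samples are assigned to
#' contiguous segments and downstream differentiation never crosses a
#' segment boundary.
#'
#' @param time_s numeric, strictly increasing seconds since experiment start.
#' @param co2_ppm numeric, finite CO2 concentrations (ppm by volume).
#' @param sensor_id character scalar identifying the sensor.
#' @param location `"inside"` (in-dish) or `"room"`.
#' @param calibrated logical; has the calibration line been applied?
#' @param gap_s gap threshold in seconds: a time step larger than this starts
#'   a new segment. Default `NULL` uses 5x the median sampling interval
#'   (at least 10 s).
#' @return A data frame of class `sensor_trace` with columns `time_s`,
#'   `co2_ppm`, `segment`, and attributes `sensor_id`, `location`,
#'   `calibrated`, `gap_s`.
#' @export
sensor_trace <- function(time_s, co2_ppm, sensor_id = "sensor",
                         location = c("inside", "room"),
                         calibrated = FALSE, gap_s = NULL) {
  location <- match.arg(location)
  time_s <- as.numeric(time_s)
  co2_ppm <- as.numeric(co2_ppm)
  if (length(time_s) != length(co2_ppm)) {
    stop("time_s and co2_ppm must have equal length", call. = FALSE)
  }
  if (length(time_s) == 0L) stop("empty trace", call. = FALSE)
  if (anyNA(time_s) || any(!is.finite(co2_ppm))) {
    stop("trace values must be finite", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    stop("time_s must be strictly increasing (first violation at index ",
         which(dt <= 0)[1] + 1L, ")", call. = FALSE)
  }
  if (is.null(gap_s)) {
    gap_s <- if (length(dt)) max(5 * median(dt), 10) else Inf
  }
  segment <- c(0L, cumsum(dt > gap_s)) + 1L
  out <- data.frame(time_s = time_s, co2_ppm = co2_ppm, segment = segment)
  structure(out,
            class = c("sensor_trace", "data.frame"),
            sensor_id = sensor_id, location = location,
            calibrated = calibrated, gap_s = gap_s)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %s (%s), %d samples, %d segment(s), %s\n",
              attr(x, "sensor_id"), attr(x, "location"), nrow(x),
              max(x$segment), if (attr(x, "calibrated")) "calibrated" else "raw"))
  cat(sprintf("  time %.0f..%.0f s, CO2 %.1f..%.1f ppm\n",
              min(x$time_s), max(x$time_s), min(x$co2_ppm), max(x$co2_ppm)))
  invisible(x)
}

# rebuild a trace with new values, keeping metadata
trace_with <- function(trace, time_s = trace$time_s, co2_ppm = trace$co2_ppm,
                       calibrated = attr(trace, "calibrated"),
                       gap_s = attr(trace, "gap_s")) {
  sensor_trace(time_s, co2_ppm,
               sensor_id = attr(trace, "sensor_id"),
               location = attr(trace, "location"),
               calibrated = calibrated,
               gap_s = gap_s)
}

#' Read a sensor log CSV
#'
#' Expects a two-column CSV with header `time_s, co2_ppm` (extra columns are
#' ignored). Duplicate timestamps are collapsed by their mean reading; time
#' must be strictly increasing after that.
#'
#' @param path path to the CSV file.
#' @param location sensor location, `"inside"` or `"room"`.
#' @param sensor_id sensor identifier; default the file name without extension.
#' @param calibrated logical flag to set on the returned trace.
#' @param gap_s see [sensor_trace()].
#' @return A [sensor_trace()].
#' @export
read_sensor_csv <- function(path, location = c("inside", "room"),
                            sensor_id = NULL, calibrated = FALSE,
                            gap_s = NULL) {
  location <- match.arg(location)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("time_s", "co2_ppm")
  if (!all(need %in% names(raw))) {
    stop("sensor CSV must have columns time_s, co2_ppm", call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(raw$time_s))
  c_ppm <- suppressWarnings(as.numeric(raw$co2_ppm))
  bad <- which(is.na(t) | is.na(c_ppm))
  if (length(bad)) {
    stop("malformed sensor CSV row at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  # collapse duplicated timestamps by mean
  if (anyDuplicated(t)) {
    c_ppm <- as.numeric(tapply(c_ppm, factor(t, levels = unique(t)), mean))
    t <- unique(t)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time_s not strictly increasing after deduplication in ", path,
         call. = FALSE)
  }
  if (is.null(sensor_id)) sensor_id <- sub("\\.[^.]*$", "", basename(path))
  sensor_trace(t, c_ppm, sensor_id = sensor_id, location = location,
               calibrated = calibrated, gap_s = gap_s)
}

#' Write a sensor trace as CSV
#'
#' Writes the two-column dialect that [read_sensor_csv()] reads, at full
#' double precision so that a write/read round trip is exact.
#'
#' @param trace a [sensor_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  df <- data.frame(time_s = format(trace$time_s, digits = 17, trim = TRUE),
                   co2_ppm = format(trace$co2_ppm, digits = 17, trim = TRUE))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Light/dark schedule
#'
#' Diel illumination schedule of the growth room. The photoperiod and dark
#' period must tile 24 h. Time 0 of a trace is assumed to coincide with a
#' phase transition into `t0_phase`, offset by `t0_offset_s` into that phase.
#'
#' @param photoperiod_h hours of light per day (default 16).
#' @param dark_h hours of dark per day (default 8).
#' @param t0_phase phase in effect at trace time 0.
#' @param t0_offset_s seconds already elapsed of that phase at time 0.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(photoperiod_h = 16, dark_h = 8,
                           t0_phase = c("light", "dark"), t0_offset_s = 0) {
  t0_phase <- match.arg(t0_phase)
  if (photoperiod_h + dark_h != 24) {
    stop("photoperiod_h + dark_h must equal 24", call. = FALSE)
  }
  if (t0_offset_s < 0) stop("t0_offset_s must be >= 0", call. = FALSE)
  structure(list(photoperiod_h = photoperiod_h, dark_h = dark_h,
                 t0_phase = t0_phase, t0_offset_s = t0_offset_s),
            class = "light_schedule")
}

#' Phase state at given trace times
#'
#' @param schedule a [light_schedule()].
#' @param time_s numeric vector of trace times (s).
#' @return A data frame with `phase` ("light"/"dark") and
#'   `t_since_transition_s` for every time point.
#' @export
schedule_phase <- function(schedule, time_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  lp <- schedule$photoperiod_h * 3600
  dp <- schedule$dark_h * 3600
  # fold onto a 24-h cycle starting at light-on
  off <- if (schedule$t0_phase == "light") schedule$t0_offset_s else
    lp + schedule$t0_offset_s
  tc <- (time_s + off) %% 86400
  light <- tc < lp
  tsince <- ifelse(light, tc, tc - lp)
  data.frame(phase = ifelse(light, "light", "dark"),
             t_since_transition_s = tsince)
}
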