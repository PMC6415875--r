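#' Invert the chamber mass balance to the plant CO2 exchange rate
#'
#' The core computation: from calibrated, 60-s averaged, synchronized
#' in-dish and room traces, recover
#' `J_plant(t) = [V dC_in/dt - (D_eff/Dx) A_seal (C_out - C_in)] / A_plant(t)`
#' in umol m-2 s-1 (uptake negative, release positive). Concentrations are
#' converted to mol m-3 with the ideal-gas law; the derivative uses central
#' differences on the averaged grid (one-sided at segment boundaries, never
#' across duty-cycle gaps); the membrane correction uses the instantaneous
#' concentration difference.
#'
#' @param inside,outside calibrated [sensor_trace()]s on the averaged grid.
#' @param seal a [seal_properties()].
#' @param geometry a [dish_geometry()].
#' @param area_fn leaf area: a function of trace time (s) returning m^2, a
#'   single positive number, or a vector matching the inside trace.
#' @param schedule optional [light_schedule()] used to annotate phases.
#' @param T_K,P_Pa temperature (K) and pressure (Pa) for the molar
#'   conversion.
#' @param sync_tol_s maximum allowed timestamp offset when aligning the room
#'   trace to the in-dish trace (default 30 s).
#' @return A `flux_series` data frame: `time_s`, `J_umol_m2_s`,
#'   `membrane_term_umol_m2_s` (the subtracted membrane contribution per leaf
#'   area), `area_m2`, and `phase` if a schedule was given; parameters are
#'   attached as attributes.
#' @export
invert_flux <- function(inside, outside, seal, geometry = dish_geometry(),
                        area_fn, schedule = NULL,
                        T_K = 294.15, P_Pa = 101325, sync_tol_s = 30) {
  stopifnot(inherits(inside, "sensor_trace"),
            inherits(outside, "sensor_trace"),
            inherits(seal, "seal_properties"))
  if (!attr(inside, "calibrated") || !attr(outside, "calibrated")) {
    stop("invert_flux requires calibrated traces", call. = FALSE)
  }
  A <- if (is.function(area_fn)) area_fn(inside$time_s)
       else if (length(area_fn) == 1L) rep(area_fn, nrow(inside))
       else area_fn
  if (length(A) != nrow(inside)) {
    stop("area_fn must yield one area per inside sample", call. = FALSE)
  }
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("leaf area must be positive over the analysis window", call. = FALSE)
  }
  C_out_ppm <- align_traces(inside, outside, tol_s = sync_tol_s)
  C_in <- ppm_to_molar(inside$co2_ppm, T_K, P_Pa)
  C_out <- ppm_to_molar(C_out_ppm, T_K, P_Pa)
  dCdt <- trace_derivative(inside$time_s, C_in, inside$segment)
  g <- seal_conductance(seal, geometry)                 # m^3/s
  membrane <- g * (C_out - C_in)                        # mol/s into the dish
  J <- (geometry$volume_m3 * dCdt - membrane) / A * 1e6 # umol m-2 s-1
  out <- data.frame(time_s = inside$time_s, J_umol_m2_s = J,
                    membrane_term_umol_m2_s = membrane / A * 1e6,
                    area_m2 = A)
  if (!is.null(schedule)) {
    ph <- schedule_phase(schedule, inside$time_s)
    out$phase <- ph$phase
    out$t_since_transition_s <- ph$t_since_transition_s
  }
  structure(out, class = c("flux_series", "data.frame"),
            seal = seal, geometry = geometry, T_K = T_K, P_Pa = P_Pa)
}

#' Label a trace with light/dark intervals
#'
#' @param trace a [sensor_trace()] (or any data frame with `time_s`).
#' @param schedule a [light_schedule()].
#' @return A list: `labels` (phase per sample) and `intervals` (data frame
#'   `start_s`, `end_s`, `phase` tiling the trace span).
#' @export
segment_periods <- function(trace, schedule) {
  ph <- schedule_phase(schedule, trace$time_s)
  t0 <- min(trace$time_s); t1 <- max(trace$time_s)
  lp <- schedule$photoperiod_h * 3600
  off <- if (schedule$t0_phase == "light") schedule$t0_offset_s else
    lp + schedule$t0_offset_s
  # transition times (light-on and light-off) covering [t0, t1]
  k <- seq(floor((t0 + off) / 86400) - 1, ceiling((t1 + off) / 86400) + 1)
  trans <- sort(c(k * 86400 - off, k * 86400 + lp - off))
  trans <- trans[trans > t0 & trans < t1]
  bounds <- c(t0, trans, t1)
  mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
  phases <- schedule_phase(schedule, mids)$phase
  list(labels = ph$phase,
       intervals = data.frame(start_s = head(bounds, -1),
                              end_s = tail(bounds, -1), phase = phases))
}

#' Per-day light- and dark-period mean concentrations
#'
#' @param trace a [sensor_trace()].
#' @param schedule a [light_schedule()].
#' @param min_coverage fraction of a phase that must be sampled for its mean
#'   to be considered well covered (default 0.5); lower coverage sets
#'   `flagged`.
#' @return Data frame `day`, `phase`, `mean_ppm`, `coverage`, `flagged`.
#'   Phases with no samples are absent (missing), never zero.
#' @export
period_means <- function(trace, schedule, min_coverage = 0.5) {
  stopifnot(inherits(schedule, "light_schedule"))
  ph <- schedule_phase(schedule, trace$time_s)
  lp <- schedule$photoperiod_h * 3600
  off <- if (schedule$t0_phase == "light") schedule$t0_offset_s else
    lp + schedule$t0_offset_s
  day <- floor((trace$time_s + off) / 86400)
  key <- interaction(day, ph$phase, drop = TRUE)
  dt <- if (nrow(trace) > 1L) median(diff(trace$time_s)) else NA_real_
  agg <- data.frame(
    day = as.integer(tapply(day, key, `[`, 1)),
    phase = as.character(tapply(ph$phase, key, `[`, 1)),
    mean_ppm = as.numeric(tapply(trace$co2_ppm, key, mean)),
    n = as.integer(table(key))
  )
  phase_len <- ifelse(agg$phase == "light", lp, schedule$dark_h * 3600)
  agg$coverage <- if (is.na(dt)) NA_real_ else pmin(agg$n * dt / phase_len, 1)
  agg$flagged <- !is.na(agg$coverage) & agg$coverage < min_coverage
  agg$n <- NULL
  agg[order(agg$day, agg$phase), , drop = FALSE]
}

#' Extreme concentration rates of change after each transition
#'
#' On a 60-s averaged trace, computes the most negative and most positive
#' first difference (in ppm/min) within a window after every light/dark
#' transition covered by the trace.
#'
#' @param trace a 60-s averaged [sensor_trace()].
#' @param schedule a [light_schedule()].
#' @param window_s post-transition search window (default 2 h).
#' @return Data frame `transition_s`, `to_phase`, `max_decrease_ppm_min`,
#'   `max_increase_ppm_min` (NA when the window has fewer than 2 points).
#' @export
max_rate_of_change <- function(trace, schedule, window_s = 7200) {
  seg <- segment_periods(trace, schedule)
  iv <- seg$intervals
  out <- lapply(seq_len(nrow(iv)), function(i) {
    t0 <- iv$start_s[i]
    sel <- trace$time_s >= t0 & trace$time_s <= min(t0 + window_s, iv$end_s[i])
    if (sum(sel) < 2L) {
      return(data.frame(transition_s = t0, to_phase = iv$phase[i],
                        max_decrease_ppm_min = NA_real_,
                        max_increase_ppm_min = NA_real_))
    }
    r <- diff(trace$co2_ppm[sel]) / diff(trace$time_s[sel]) * 60
    data.frame(transition_s = t0, to_phase = iv$phase[i],
               max_decrease_ppm_min = min(c(r, 0)),
               max_increase_ppm_min = max(c(r, 0)))
  })
  do.call(rbind, out)
}
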