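#' De-dimensionalize a concentration trace
#'
#' Scales a trace to the dimensionless form
#' `(C(t) - C_avg) / (C_max - C_avg)`, where `C_avg` is the overall mean and
#' `C_max` the maximum over the analysis window. The scaled value at the
#' maximum is exactly 1, and the transform is invariant to affine changes of
#' the concentration axis (so it commutes with linear sensor calibration).
#'
#' @param trace a [sensor_trace()] (non-constant).
#' @return A data frame `time_s`, `scaled` with attributes `C_avg`, `C_max`.
#' @export
dedimensionalize <- function(trace) {
  stopifnot(inherits(trace, "sensor_trace"))
  C_avg <- mean(trace$co2_ppm)
  C_max <- max(trace$co2_ppm)
  if (C_max - C_avg <= 0) {
    stop("degenerate scaling: trace is constant (C_max == C_avg)",
         call. = FALSE)
  }
  structure(data.frame(time_s = trace$time_s,
                       scaled = (trace$co2_ppm - C_avg) / (C_max - C_avg)),
            C_avg = C_avg, C_max = C_max)
}

# time derivative by central differences within segments, one-sided at
# segment boundaries; never across gaps
trace_derivative <- function(time_s, values, segment = rep(1L, length(time_s))) {
  n <- length(time_s)
  d <- rep(NA_real_, n)
  for (s in unique(segment)) {
    i <- which(segment == s)
    m <- length(i)
    if (m < 2L) next
    t <- time_s[i]; v <- values[i]
    di <- numeric(m)
    if (m > 2L) {
      di[2:(m - 1)] <- (v[3:m] - v[1:(m - 2)]) / (t[3:m] - t[1:(m - 2)])
    }
    di[1] <- (v[2] - v[1]) / (t[2] - t[1])
    di[m] <- (v[m] - v[m - 1]) / (t[m] - t[m - 1])
    d[i] <- di
  }
  d
}

# align `other` onto the timestamps of `ref` by nearest neighbour within tol
align_traces <- function(ref, other, tol_s = 30) {
  idx <- vapply(ref$time_s, function(t) which.min(abs(other$time_s - t)),
                integer(1))
  off <- abs(other$time_s[idx] - ref$time_s)
  if (any(off > tol_s)) {
    stop(sprintf("traces not synchronized: offset up to %.1f s exceeds %g s",
                 max(off), tol_s), call. = FALSE)
  }
  other$co2_ppm[idx]
}

#' Estimate seal permeability and effective diffusivity from a box decay
#'
#' From synchronized in-dish and box traces of a box-decay experiment, each
#' time point yields a Fick's-law estimate
#' `D_t = V * (dC_in/dt) * Dx / (A_seal * (C_out - C_in))`.
#' The derivative is taken by central differences on 60-s averaged data
#' (one-sided at segment boundaries, never across gaps). Points where the
#' remaining gradient |C_out - C_in| has decayed below `exclusion_frac` of
#' its initial value are excluded to avoid division blow-up near
#' equilibrium. The estimate is the mean over retained points, with its
#' standard error. Because the estimator is a ratio of a concentration rate
#' to a concentration difference, it is invariant to the ppm/molar unit
#' conversion; traces may be supplied in ppm.
#'
#' @param inside,outside calibrated [sensor_trace()]s (in-dish and box).
#' @param geometry a [dish_geometry()].
#' @param thickness_m seal thickness Dx (m).
#' @param exclusion_frac gradient-decay exclusion threshold (default 0.1).
#' @param window_s averaging window before differentiation (default 60 s;
#'   `NULL` to use the traces as given).
#' @param seal seal label recorded on the result.
#' @return A [seal_properties()] with estimated `D_eff_m2s`, `D_se_m2s`,
#'   `permeability_m_s`, plus attributes `points` (the per-point `D_t` table)
#'   and `sign_warning` (TRUE when flux and gradient disagree in sign for
#'   more than half of the retained points).
#' @export
estimate_permeability <- function(inside, outside, geometry = dish_geometry(),
                                  thickness_m, exclusion_frac = 0.1,
                                  window_s = 60,
                                  seal = c("parafilm", "micropore")) {
  seal <- match.arg(seal)
  stopifnot(inherits(inside, "sensor_trace"), inherits(outside, "sensor_trace"))
  if (!is.null(window_s)) {
    inside <- average_window(inside, window_s)
    outside <- average_window(outside, window_s)
  }
  C_out <- align_traces(inside, outside)
  dCdt <- trace_derivative(inside$time_s, inside$co2_ppm, inside$segment)
  grad <- C_out - inside$co2_ppm
  keep <- is.finite(dCdt) & abs(grad) > 0 &
    abs(grad) >= exclusion_frac * abs(grad[1])
  if (!any(keep)) {
    stop("all points excluded: no usable concentration gradient",
         call. = FALSE)
  }
  D_t <- geometry$volume_m3 * dCdt[keep] * thickness_m /
    (geometry$seal_area_m2 * grad[keep])
  sign_warning <- mean(dCdt[keep] * grad[keep] < 0) > 0.5
  if (sign_warning) {
    warning("flux and gradient sign-inconsistent in > 50% of points",
            call. = FALSE)
  }
  D_mean <- mean(D_t)
  D_se <- if (length(D_t) > 1L) sd(D_t) / sqrt(length(D_t)) else NA_real_
  out <- seal_properties(seal, thickness_m = thickness_m,
                         D_eff_m2s = D_mean, D_se_m2s = D_se)
  attr(out, "points") <- data.frame(time_s = inside$time_s[keep], D_t = D_t)
  attr(out, "sign_warning") <- sign_warning
  attr(out, "exclusion_frac") <- exclusion_frac
  out
}
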