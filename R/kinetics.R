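#' Fit exponential relaxation kinetics after a light/dark transition
#'
#' After each transition the exchange rate typically shoots to an extremum
#' and then relaxes exponentially toward a steady state. This fits
#' `J(t) = J_ss + (J_peak - J_ss) * exp(-(t - t_peak)/tau)` to a flux series:
#' the peak time is the argmax of |J| within a post-transition search window
#' (earliest time on ties) and the observed extremum there is reported as
#' `J_max`; `J_ss`, `tau` and the fitted peak amplitude `J_peak`
#' (initialized at the observed extremum) are estimated by least squares on
#' the window from the peak to the end of the phase, excluding the final
#' `tail_guard_s` before the next transition. Freeing the amplitude keeps
#' `tau` unbiased when the single peak sample carries sensor noise.
#'
#' @param flux a `flux_series` from [invert_flux()], or any data frame with
#'   `time_s` and `J_umol_m2_s`.
#' @param transition_s trace time of the transition (s).
#' @param phase_end_s trace time when the phase ends.
#' @param peak_window_s search window for the extremum after the transition
#'   (default 15 min).
#' @param tail_guard_s data excluded before `phase_end_s` (default 5 min).
#' @return An `exponential_kinetics` list: `transition_s`, `t_peak_s` (since
#'   transition), `J_max` (observed extremum), `J_peak` (fitted peak
#'   amplitude), `J_ss`, `tau_s`, `tau_min`, `r_squared`, `fit_window_s`,
#'   `n_points`, `undefined` (TRUE when no interior extremum exists, in
#'   which case only a steady-state summary is returned).
#' @export
fit_transition_kinetics <- function(flux, transition_s, phase_end_s,
                                    peak_window_s = 15 * 60,
                                    tail_guard_s = 5 * 60) {
  t <- flux$time_s
  J <- flux$J_umol_m2_s
  insearch <- which(t >= transition_s & t <= transition_s + peak_window_s)
  if (length(insearch) < 3L) {
    stop("peak-search window contains fewer than 3 flux points",
         call. = FALSE)
  }
  absJ <- abs(J[insearch])
  ipk <- insearch[which.max(absJ)]  # which.max: earliest index on ties
  t_peak <- t[ipk]
  J_max <- J[ipk]

  fit_sel <- which(t >= t_peak & t <= phase_end_s - tail_guard_s)
  base <- list(transition_s = transition_s, t_peak_s = t_peak - transition_s,
               J_max = J_max,
               fit_window_s = c(t_peak, phase_end_s - tail_guard_s))

  # an interior extremum is required: a flux with no contrast over the
  # window, or one still rising beyond the window edge, has no relaxation
  # to fit. An edge argmax with declining flux afterwards is accepted as a
  # (possibly noise-displaced) peak: the relaxation fit below re-estimates
  # the amplitude, so tau and J_ss do not depend on the exact peak sample.
  spread <- diff(range(absJ))
  still_rising <- FALSE
  if (ipk == max(insearch)) {
    step <- median(diff(t[insearch]))
    after <- which(t > t[ipk] & t <= t[ipk] + 3 * step)
    last3 <- tail(insearch, 3)
    still_rising <- length(after) == 0L ||
      mean(abs(J[after])) > mean(abs(J[last3]))
  }
  if (still_rising || spread < 1e-9 * max(absJ, 1e-12)) {
    tailJ <- J[fit_sel]
    return(structure(c(base, list(
      J_peak = NA_real_, J_ss = mean(tailJ), tau_s = NA_real_,
      tau_min = NA_real_, r_squared = NA_real_,
      n_points = length(fit_sel), undefined = TRUE)),
      class = "exponential_kinetics"))
  }

  tt <- t[fit_sel] - t_peak
  y <- J[fit_sel]
  # profile tau on a log grid: for fixed tau the model is linear in
  # (J_ss, J_peak), so the conditional optimum is a plain regression; this
  # gives a robust start (and fallback) for the nonlinear refinement
  taugrid <- exp(seq(log(30), log(max(tt)), length.out = 60))
  prof <- lapply(taugrid, function(tau) {
    x <- exp(-tt / tau)
    f <- lm(y ~ x)
    list(tau = tau, sse = sum(f$residuals^2),
         J_ss = unname(coef(f)[1]),
         J_peak = unname(coef(f)[1] + coef(f)[2]))
  })
  best <- prof[[which.min(vapply(prof, `[[`, 0, "sse"))]]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ J_ss + (J_peak - J_ss) * exp(-tt / tau),
      start = list(J_ss = best$J_ss, J_peak = best$J_peak, tau = best$tau),
      lower = c(J_ss = -Inf, J_peak = -Inf, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- c(J_ss = best$J_ss, J_peak = best$J_peak, tau = best$tau)
    resid <- y - (best$J_ss + (best$J_peak - best$J_ss) * exp(-tt / best$tau))
  } else {
    co <- coef(fit)
    resid <- y - predict(fit)
  }
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(c(base, list(
    J_peak = unname(co["J_peak"]),
    J_ss = unname(co["J_ss"]), tau_s = unname(co["tau"]),
    tau_min = unname(co["tau"]) / 60,
    r_squared = max(0, min(1, r2)), n_points = length(y),
    undefined = FALSE)), class = "exponential_kinetics")
}

#' @export
print.exponential_kinetics <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf(
      "<exponential_kinetics> no interior extremum; steady state %.3g umol m-2 s-1\n",
      x$J_ss))
  } else {
    cat(sprintf(
      "<exponential_kinetics> J_max %.4g, J_ss %.4g umol m-2 s-1, tau %.3g min (R^2 %.3f)\n",
      x$J_max, x$J_ss, x$tau_min, x$r_squared))
  }
  invisible(x)
}

#' Steady-state flux over a phase tail
#'
#' Mean and standard error of the flux over the final `tail_frac` of a
#' phase, as a model-free steady-state estimate.
#'
#' @param flux a `flux_series` (or data frame with `time_s`, `J_umol_m2_s`).
#' @param phase_start_s,phase_end_s phase boundaries (trace time, s).
#' @param tail_frac fraction of the phase to use (default 0.25).
#' @param min_samples minimum number of samples required (default 10).
#' @return List `mean`, `se`, `sd`, `n`; all NA when the tail has fewer than
#'   `min_samples` points.
#' @export
steady_state_flux <- function(flux, phase_start_s, phase_end_s,
                              tail_frac = 0.25, min_samples = 10L) {
  t0 <- phase_end_s - tail_frac * (phase_end_s - phase_start_s)
  sel <- flux$time_s >= t0 & flux$time_s <= phase_end_s
  J <- flux$J_umol_m2_s[sel]
  if (length(J) < min_samples) {
    return(list(mean = NA_real_, se = NA_real_, sd = NA_real_,
                n = length(J)))
  }
  list(mean = mean(J), se = sd(J) / sqrt(length(J)), sd = sd(J),
       n = length(J))
}
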