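#' Segment leaf area from a plate photograph
#'
#' Counts pixels falling inside an HSV window (default: green hues 60-180
#' deg with saturation and value at least 0.15) and converts the count to an
#' area through the imaging scale. This reimplements the usual
#' color-threshold-to-binary workflow used for rosette area measurement.
#'
#' @param image RGB array (h x w x 3, values in \[0, 1\]).
#' @param scale_m_per_px physical size of one pixel (m), > 0.
#' @param hue_deg length-2 hue window in degrees.
#' @param min_s,min_v minimum saturation and value.
#' @return Area in m^2, with attribute `n_pixels`. Zero matching pixels
#'   gives 0 with a warning.
#' @export
segment_leaf_area <- function(image, scale_m_per_px,
                              hue_deg = c(60, 180),
                              min_s = 0.15, min_v = 0.15) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L)) {
    stop("image must be an h x w x 3 RGB array", call. = FALSE)
  }
  if (!is.finite(scale_m_per_px) || scale_m_per_px <= 0) {
    stop("scale_m_per_px must be > 0", call. = FALSE)
  }
  hsv <- rgb2hsv(r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
                 b = as.vector(image[, , 3]), maxColorValue = 1)
  h <- hsv[1, ] * 360
  inwin <- h >= hue_deg[1] & h <= hue_deg[2] &
    hsv[2, ] >= min_s & hsv[3, ] >= min_v
  n <- sum(inwin)
  if (n == 0L) warning("no pixels matched the hue window", call. = FALSE)
  structure(n * scale_m_per_px^2, n_pixels = n)
}

#' Fit a power-law growth curve to leaf areas
#'
#' Least-squares fit of `A = a * t^b` on the log-log scale (days since
#' sowing vs area). Zero-area days are excluded (with a warning) before the
#' log transform; at least 3 positive pairs are required.
#'
#' @param days days since sowing (> 0).
#' @param areas_m2 areas (m^2).
#' @return A `leaf_area_fit`: the [leaf_area_law()] plus `r_squared` (in log
#'   space), `n`, and the day range used.
#' @export
fit_power_law <- function(days, areas_m2) {
  if (length(days) != length(areas_m2)) {
    stop("days and areas_m2 must have equal length", call. = FALSE)
  }
  if (any(areas_m2 < 0)) stop("areas must be nonnegative", call. = FALSE)
  zero <- areas_m2 == 0
  if (any(zero)) {
    warning(sum(zero), " zero-area day(s) excluded from the power-law fit",
            call. = FALSE)
    days <- days[!zero]; areas_m2 <- areas_m2[!zero]
  }
  if (any(days <= 0)) stop("days must be > 0 for the log-log fit", call. = FALSE)
  if (length(days) < 3L) {
    stop("power-law fit needs at least 3 positive (day, area) pairs",
         call. = FALSE)
  }
  fit <- lm(log(areas_m2) ~ log(days))
  # suppressed: summary.lm warns on exact (zero-residual) fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  law <- leaf_area_law(a = exp(unname(coef(fit)[1])),
                       b = unname(coef(fit)[2]))
  structure(c(law, list(r_squared = r2, n = length(days),
                        day_range = range(days))),
            class = c("leaf_area_fit", "leaf_area_law"))
}

#' Evaluate a fitted leaf-area law on a time grid
#'
#' Interpolates (via the fitted power law) the leaf area on an arbitrary
#' grid, typically the 60-s grid of the averaged CO2 trace. Evaluation
#' outside the observed day range is refused unless `extrapolate = TRUE`.
#'
#' @param fit a [fit_power_law()] result (or any [leaf_area_law()], in which
#'   case no range check applies).
#' @param day_grid days since sowing at which to evaluate.
#' @param extrapolate allow evaluation outside the fitted day range.
#' @return Areas in m^2.
#' @export
interpolate_area <- function(fit, day_grid, extrapolate = FALSE) {
  if (inherits(fit, "leaf_area_fit") && !extrapolate) {
    rng <- fit$day_range
    if (any(day_grid < rng[1] | day_grid > rng[2])) {
      stop(sprintf(
        "grid outside observed days [%g, %g]; set extrapolate = TRUE",
        rng[1], rng[2]), call. = FALSE)
    }
  }
  leaf_area_at(fit, day_grid)
}
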