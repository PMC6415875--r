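#' Petri-dish chamber geometry
#'
#' Geometry of the sealed square Petri dish used as the gas-exchange chamber.
#' The seal area is the perimeter of the dish times the width of the gap
#' between top and bottom plates (the four sealed faces are treated as one
#' membrane of that area). Defaults are for a standard 10 cm x 10 cm square
#' dish: volume 1.1e-4 m^3, perimeter 0.4 m, gap 1 mm, seal area 4e-4 m^2.
#'
#' @param volume_m3 internal air volume (m^3).
#' @param perimeter_m dish perimeter (m).
#' @param gap_width_m width of the sealed gap between plates (m).
#' @param seal_area_m2 seal area (m^2); must equal `perimeter_m * gap_width_m`.
#' @return An object of class `dish_geometry`.
#' @export
dish_geometry <- function(volume_m3 = 1.1e-4, perimeter_m = 0.4,
                          gap_width_m = 0.001,
                          seal_area_m2 = perimeter_m * gap_width_m) {
  vals <- c(volume_m3, perimeter_m, gap_width_m, seal_area_m2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be positive", call. = FALSE)
  }
  if (abs(seal_area_m2 - perimeter_m * gap_width_m) >
      1e-12 * seal_area_m2) {
    stop("seal_area_m2 must equal perimeter_m * gap_width_m", call. = FALSE)
  }
  structure(list(volume_m3 = volume_m3, perimeter_m = perimeter_m,
                 gap_width_m = gap_width_m, seal_area_m2 = seal_area_m2),
            class = "dish_geometry")
}

#' Seal membrane properties
#'
#' Effective diffusivity and thickness of the film sealing the dish.
#' Defaults are measured values for the two common seals: stretched Parafilm
#' (thickness 46.9 um, D_eff 1.0e-9 m^2/s) and Micropore surgical tape
#' (thickness 67.9 um, D_eff 8e-8 m^2/s). The permeability is D_eff / Dx.
#'
#' @param seal `"parafilm"` or `"micropore"`; selects default thickness and
#'   diffusivity, either of which can be overridden.
#' @param thickness_m membrane thickness Dx (m).
#' @param D_eff_m2s effective diffusivity of CO2 through the membrane (m^2/s).
#' @param D_se_m2s optional standard error of `D_eff_m2s`.
#' @return An object of class `seal_properties` with fields `seal`,
#'   `thickness_m`, `D_eff_m2s`, `permeability_m_s`, `D_se_m2s`.
#' @export
seal_properties <- function(seal = c("parafilm", "micropore"),
                            thickness_m = NULL, D_eff_m2s = NULL,
                            D_se_m2s = NA_real_) {
  seal <- match.arg(seal)
  defaults <- list(
    parafilm  = list(thickness_m = 46.9e-6, D_eff_m2s = 1.0e-9),
    micropore = list(thickness_m = 67.9e-6, D_eff_m2s = 8e-8)
  )[[seal]]
  if (is.null(thickness_m)) thickness_m <- defaults$thickness_m
  if (is.null(D_eff_m2s)) D_eff_m2s <- defaults$D_eff_m2s
  if (!is.finite(thickness_m) || thickness_m <= 0 ||
      !is.finite(D_eff_m2s) || D_eff_m2s <= 0) {
    stop("thickness_m and D_eff_m2s must be positive", call. = FALSE)
  }
  structure(list(seal = seal, thickness_m = thickness_m,
                 D_eff_m2s = D_eff_m2s,
                 permeability_m_s = D_eff_m2s / thickness_m,
                 D_se_m2s = D_se_m2s),
            class = "seal_properties")
}

#' @export
print.seal_properties <- function(x, ...) {
  cat(sprintf(
    "<seal_properties> %s: Dx = %.3g m, D_eff = %.3g m^2/s, D/Dx = %.3g m/s\n",
    x$seal, x$thickness_m, x$D_eff_m2s, x$permeability_m_s))
  invisible(x)
}

# membrane volumetric conductance (m^3/s): (D/Dx) * A_seal
seal_conductance <- function(seal, geometry) {
  seal$permeability_m_s * geometry$seal_area_m2
}
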