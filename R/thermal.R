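#' Thermal parameters for steady-state nanoparticle heating
#'
#' The dimensionless thermal capacitance coefficient beta equals 1 for a
#' sphere and grows as the shape elongates (better surface-to-volume
#' heat release). The shipped default table is a placeholder consistent
#' with that qualitative behavior (boundary-element tabulations exist in
#' the literature but are not bundled); it is linearly interpolated in
#' aspect ratio and fully replaceable via configuration.
#'
#' @param kappa_water Thermal conductivity of the medium, W m-1 K-1
#'   (default 0.6, water).
#' @param beta_table Named mapping aspect ratio -> beta; non-decreasing,
#'   beta(1) = 1.
#' @param dT_target Target steady-state temperature rise in K.
#' @return A `thermal_params` object.
#' @export
thermal_params <- function(kappa_water = 0.6,
                           beta_table = c("1" = 1.00, "2" = 1.08, "3" = 1.18,
                                          "4" = 1.28, "5" = 1.37),
                           dT_target = 10) {
  stopifnot(kappa_water > 0, dT_target > 0, all(beta_table >= 1))
  ar <- as.numeric(names(beta_table))
  stopifnot(!any(is.na(ar)), all(diff(ar) > 0), all(diff(beta_table) >= 0))
  structure(list(kappa_water = kappa_water,
                 beta_ar = ar, beta_values = unname(beta_table),
                 dT_target = dT_target),
            class = "thermal_params")
}

#' Thermal capacitance coefficient for an aspect ratio
#'
#' Linear interpolation of the beta table; constant extrapolation at the
#' table ends.
#'
#' @param params A `thermal_params`.
#' @param aspect_ratio Rod aspect ratio (>= 1).
#' @return Dimensionless beta (>= 1).
#' @export
beta_coefficient <- function(params, aspect_ratio) {
  stopifnot(inherits(params, "thermal_params"), all(aspect_ratio >= 1))
  stats::approx(params$beta_ar, params$beta_values, xout = aspect_ratio,
                rule = 2)$y
}

#' Steady-state surface temperature rise of an illuminated nanoparticle
#'
#' `dT = C_abs I / (4 pi kappa R_eq beta)`: absorbed power
#' `P = C_abs I` released through a medium of conductivity kappa, with
#' the volume-equivalent sphere radius and the shape's thermal
#' capacitance coefficient.
#'
#' @param C_abs Absorption cross section at the heating wavelength, um2.
#' @param intensity Illumination intensity, W/m2.
#' @param R_eq Volume-equivalent sphere radius, nm.
#' @param beta Thermal capacitance coefficient (1 for a sphere).
#' @param kappa Medium thermal conductivity, W m-1 K-1.
#' @return Temperature rise in K.
#' @export
steady_state_dT <- function(C_abs, intensity, R_eq, beta = 1, kappa = 0.6) {
  stopifnot(all(C_abs >= 0), all(intensity >= 0), all(R_eq > 0),
            all(beta >= 1), kappa > 0)
  p_abs <- C_abs * 1e-12 * intensity          # W
  p_abs / (4 * pi * kappa * (R_eq * 1e-9) * beta)
}

#' Illumination intensity producing a target temperature rise
#'
#' Inverse of [steady_state_dT()]:
#' `I = 4 pi kappa R_eq beta dT / C_abs`.
#'
#' @param C_abs Absorption cross section at the heating wavelength, um2
#'   (> 0).
#' @param R_eq Volume-equivalent sphere radius, nm.
#' @param beta Thermal capacitance coefficient.
#' @param kappa Medium thermal conductivity, W m-1 K-1.
#' @param dT_target Target temperature rise, K.
#' @return Intensity in W/m2.
#' @export
intensity_for_dT <- function(C_abs, R_eq, beta = 1, kappa = 0.6,
                             dT_target = 10) {
  stopifnot(all(R_eq > 0), all(beta >= 1), kappa > 0, dT_target > 0)
  if (any(C_abs <= 0)) stop("C_abs must be > 0 to invert the heating formula")
  4 * pi * kappa * (R_eq * 1e-9) * beta * dT_target / (C_abs * 1e-12)
}
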