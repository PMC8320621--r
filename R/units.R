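# Unit conventions used throughout: surface tension in mN/m, lengths in mm,
# areas in mm^2, volumes in uL (= mm^3), density in kg/m^3, deposition in
# ng/cm^2, time in s (deposition flux is quoted per minute, as instruments do).

#' Capillary constant in drop-scale units
#'
#' Ratio of gravitational to capillary pressure gradients,
#' \eqn{\Delta\rho g / \gamma}, expressed in 1/mm^2 so it can multiply
#' millimetre coordinates directly.
#'
#' @param delta_rho Density difference between drop and surrounding phase,
#'   kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @param gamma Surface tension, mN/m.
#' @return Capillary constant in 1/mm^2.
#' @keywords internal
capillary_constant_mm2 <- function(delta_rho, g, gamma) {
  # SI value is delta_rho*g/(gamma*1e-3) in 1/m^2; 1/m^2 = 1e-6/mm^2
  delta_rho * g / gamma * 1e-3
}

#' Bond number of a drop
#'
#' Dimensionless ratio \eqn{\Delta\rho g R_0^2 / \gamma} of gravitational to
#' capillary forces; zero for a spherical (gravity-free) drop.
#'
#' @inheritParams capillary_constant_mm2
#' @param apex_radius Radius of curvature at the drop apex, mm.
#' @return Bond number (dimensionless, >= 0).
#' @export
bond_number <- function(delta_rho, g, apex_radius, gamma) {
  capillary_constant_mm2(delta_rho, g, gamma) * apex_radius^2
}

#' Round half away from zero
#'
#' Display rounding used for reported metrics (e.g. 17/21 -> 0.81): exact
#' halves round up, unlike base round()'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector; NA passes through.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cdsurf <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cdsurf_error")))
}
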