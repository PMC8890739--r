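#' Blood-analogue fluid properties
#'
#' The working fluid of the phantom is a refractive-index-matched
#' water/glycerin/sodium-iodide blood analogue. Defaults are its measured
#' density (1221 kg m^-3) and dynamic viscosity (5e-3 Pa s); the kinematic
#' viscosity is derived as mu/rho (4.095e-6 m^2 s^-1, i.e. 4.1e-6 at two
#' significant digits).
#'
#' @param density Fluid density (kg m^-3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Object of class `aneupiv_fluid` with fields `density`,
#'   `viscosity`, `kinematic_viscosity`.
#' @export
fluid_properties <- function(density = 1221, viscosity = 5e-3) {
  if (density <= 0 || viscosity <= 0) stop("fluid properties must be positive")
  out <- list(density = density, viscosity = viscosity,
              kinematic_viscosity = viscosity / density)
  class(out) <- "aneupiv_fluid"
  out
}

#' Reference blood properties
#'
#' Physiological reference values the analogue fluid is matched against
#' (dynamic-viscosity equivalence at matched kinematic viscosity).
#'
#' @return Named list with `viscosity` (3.9e-3 Pa s) and `density`
#'   (1060 kg m^-3).
#' @export
blood_reference <- function() {
  list(viscosity = 3.9e-3, density = 1060)
}

#' Reynolds and Womersley numbers
#'
#' `reynolds_number` uses the peak centerline velocity and vessel diameter;
#' `womersley_number` uses the vessel radius and the cardiac angular
#' frequency 2*pi/T.
#'
#' @param velocity Peak velocity (m/s).
#' @param diameter Vessel diameter (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @param period Cycle duration (s).
#' @return Dimensionless number.
#' @export
reynolds_number <- function(velocity, diameter, nu) velocity * diameter / nu

#' @rdname reynolds_number
#' @export
womersley_number <- function(diameter, period, nu) {
  (diameter / 2) * sqrt(2 * pi / (period * nu))
}
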