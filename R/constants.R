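# Fixed CODATA-2018 values; everything downstream assumes strict SI.
.const <- list(
  e         = 1.602176634e-19,   # elementary charge, C
  N_A       = 6.02214076e23,     # Avogadro number, 1/mol
  k_B       = 1.380649e-23,      # Boltzmann constant, J/K
  epsilon_0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  dalton    = 1.66053906660e-27  # unified atomic mass unit, kg
)

#' Physical constants used throughout the package
#'
#' Returns the fixed CODATA 2018 values of the elementary charge, Avogadro
#' number, Boltzmann constant and vacuum permittivity (plus the dalton, used
#' to convert protein masses to kg). These are not user-configurable: every
#' derived quantity in the package (Debye length, surface charge densities,
#' energies) is computed from this single set.
#'
#' @return A named list with elements `e` (C), `N_A` (1/mol), `k_B` (J/K),
#'   `epsilon_0` (F/m) and `dalton` (kg).
#' @examples
#' si_constants()$k_B * 293.15  # thermal energy at 20 degrees C, J
#' @export
si_constants <- function() .const

#' Express an energy in units of the thermal energy k_B T
#'
#' @param energy Energy in joules (vectorised).
#' @param temperature Absolute temperature in kelvin.
#' @return `energy / (k_B * temperature)`, dimensionless.
#' @examples
#' energy_in_kBT(4.05e-21, 293.15)  # about 1
#' @export
energy_in_kBT <- function(energy, temperature) {
  stopifnot(is.numeric(energy), is.numeric(temperature), temperature > 0)
  energy / (.const$k_B * temperature)
}

# Thermal voltage k_B T / e (V); the validity bound of the linearized theory.
.thermal_voltage <- function(temperature) .const$k_B * temperature / .const$e

.stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
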