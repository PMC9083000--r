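#' Electrolyte medium
#'
#' Bundles the solvent/electrolyte state: relative permittivity, absolute
#' temperature, dynamic viscosity and the concentration of a monovalent
#' symmetric salt (KCl in all default scenarios). All fields are SI; use
#' `concentration_mM` for the usual millimolar convenience unit
#' (1 mM = 1 mol/m^3).
#'
#' @param epsilon_r Relative permittivity (dimensionless, > 1). Default 78.3
#'   (water at 20 degrees C).
#' @param temperature Absolute temperature in K (> 0). Default 293.15 K.
#' @param viscosity Dynamic viscosity in Pa s (> 0). Default 1e-3 (water).
#' @param concentration_mM Ionic concentration of the monovalent salt in mM
#'   (> 0).
#' @return An object of class `ez_medium` with fields `epsilon_r`, `T`,
#'   `eta` and `c_s` (mol/m^3).
#' @examples
#' m <- medium(concentration_mM = 10)
#' debye_length(m) * 1e9  # about 3 nm
#' @seealso [debye_length()]
#' @export
medium <- function(epsilon_r = 78.3, temperature = 293.15,
                   viscosity = 1e-3, concentration_mM = 10) {
  if (!is.numeric(epsilon_r) || length(epsilon_r) != 1L || epsilon_r <= 1)
    .stop_invalid("`epsilon_r` must be a single number > 1 (got %s)", format(epsilon_r))
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    .stop_invalid("`temperature` must be a single positive number in K")
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0)
    .stop_invalid("`viscosity` must be a single positive number in Pa s")
  if (!is.numeric(concentration_mM) || length(concentration_mM) != 1L ||
      concentration_mM <= 0)
    .stop_invalid("`concentration_mM` must be a single positive number")
  structure(
    list(epsilon_r = epsilon_r, T = temperature, eta = viscosity,
         c_s = concentration_mM),  # 1 mM of monovalent salt == 1 mol/m^3
    class = "ez_medium")
}

#' Debye screening length of a monovalent electrolyte
#'
#' Computes the characteristic screening distance
#' \deqn{\lambda_D = \sqrt{\frac{\varepsilon_0 \varepsilon_r k_B T}
#'   {2 N_A c_s e^2}}}
#' for a symmetric monovalent salt. This is the decay constant of every
#' linearized Poisson-Boltzmann potential in the package; it scales as
#' \eqn{c_s^{-1/2}}, so quadrupling the salt concentration halves the
#' screening length.
#'
#' @param medium An [medium()] object.
#' @return Debye length in metres. At 78.3 / 293.15 K this is about 3 nm at
#'   10 mM and about 7.5 Angstrom at 160 mM.
#' @export
debye_length <- function(medium) {
  stopifnot(inherits(medium, "ez_medium"))
  k <- .const
  sqrt(k$epsilon_0 * medium$epsilon_r * k$k_B * medium$T /
         (2 * k$N_A * medium$c_s * k$e^2))
}

#' Charged repelling surface
#'
#' Describes the body generating the screened electrostatic field: an
#' infinitely long cylinder (microtubule wall), a sphere (single tubulin
#' dimer) or an infinite plane (tubulin sheet). The diffuse-layer solution
#' applies outside a Stern layer of thickness `stern` (one adsorbed-K+
#' radius, 0.33 nm, in all default scenarios).
#'
#' @param kind One of `"cylinder"`, `"sphere"`, `"plane"`.
#' @param radius Body radius in m; required for cylinder and sphere, ignored
#'   (and left NA) for the plane.
#' @param stern Stern-layer thickness in m (> 0). Default 0.33e-9.
#' @param sigma Surface charge density in C/m^2. Negative for all default
#'   tubulin scenarios.
#' @return An object of class `ez_surface` with fields `kind`, `R`, `d`,
#'   `sigma`.
#' @examples
#' charged_surface("cylinder", radius = 12.5e-9, sigma = -0.102)
#' @export
charged_surface <- function(kind = c("cylinder", "sphere", "plane"),
                            radius = NULL, stern = 0.33e-9, sigma) {
  kind <- match.arg(kind)
  if (kind == "plane") {
    radius <- NA_real_
  } else {
    if (is.null(radius) || !is.numeric(radius) || length(radius) != 1L ||
        radius <= 0)
      .stop_invalid("`radius` must be a single positive length (m) for a %s", kind)
  }
  if (!is.numeric(stern) || length(stern) != 1L || stern <= 0)
    .stop_invalid("`stern` must be a single positive length (m)")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma))
    .stop_invalid("`sigma` must be a single finite charge density (C/m^2)")
  structure(list(kind = kind, R = radius, d = stern, sigma = sigma),
            class = "ez_surface")
}

#' Innermost coordinate at which the diffuse-layer field is defined
#'
#' `R + d` for cylinder and sphere, `d` for the plane.
#'
#' @param surface An [charged_surface()] object.
#' @return Coordinate in m.
#' @export
stern_boundary <- function(surface) {
  if (surface$kind == "plane") surface$d else surface$R + surface$d
}

#' Spherical-body surface charge density
#'
#' \eqn{\sigma = Q_{bare} / (4 \pi R^2)}: the bare charge spread uniformly
#' over the sphere. With the tubulin bare charge of -52 e and the 2.71 nm
#' equivalent radius this gives -0.090 C/m^2, the value used for the sphere
#' and sheet scenarios.
#'
#' @param charge Total bare charge in C.
#' @param radius Sphere radius in m (> 0).
#' @return Charge density in C/m^2, with the sign of `charge`.
#' @export
sphere_surface_charge <- function(charge, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    .stop_invalid("`radius` must be a single positive length (m)")
  stopifnot(is.numeric(charge), length(charge) == 1L)
  charge / (4 * pi * radius^2)
}

#' Microtubule surface-charge budget
#'
#' The microtubule wall charge density is an area-weighted combination of the
#' outer-wall contribution and the two C-terminal tails per dimer:
#' \eqn{\sigma = \sigma_{out} A_{out}/A_{tot} + \sigma_{CT} \, 2 A_{CT}/A_{tot}}.
#' The canonical cylinder value of -0.102 C/m^2 (charges -25 e for the outer
#' surface and -11 e per C-terminus) is stored as [mt_sigma_default]; this
#' constructor and [mt_surface_charge()] serve users who supply their own
#' area model, which the default parameterisation leaves open.
#'
#' @param sigma_out Outer-wall charge density contribution (C/m^2).
#' @param sigma_CT Per-C-terminus charge density contribution (C/m^2).
#' @param A_out,A_CT,A_tot Outer-wall, single-C-terminus and total areas
#'   (m^2, all > 0).
#' @return An object of class `ez_mt_budget`.
#' @export
mt_charge_budget <- function(sigma_out, sigma_CT, A_out, A_CT, A_tot) {
  for (nm in c("A_out", "A_CT", "A_tot")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      .stop_invalid("`%s` must be a single positive area (m^2)", nm)
  }
  stopifnot(is.numeric(sigma_out), is.numeric(sigma_CT))
  structure(list(sigma_out = sigma_out, sigma_CT = sigma_CT,
                 A_out = A_out, A_CT = A_CT, A_tot = A_tot),
            class = "ez_mt_budget")
}

#' Area-weighted microtubule surface charge density
#'
#' @param budget An [mt_charge_budget()] object.
#' @return Charge density in C/m^2.
#' @export
mt_surface_charge <- function(budget) {
  stopifnot(inherits(budget, "ez_mt_budget"))
  budget$sigma_out * budget$A_out / budget$A_tot +
    budget$sigma_CT * 2 * budget$A_CT / budget$A_tot
}

#' Canonical microtubule wall charge density
#'
#' The area-weighted cylinder charge density, -0.102 C/m^2, obtained from
#' charges of -25 e for the outer wall and -11 e per C-terminus. Stored as a
#' constant because the underlying areas have no unique parameterisation;
#' see [mt_charge_budget()] to recompute from an explicit area model.
#' @format A length-one numeric, C/m^2.
#' @export
mt_sigma_default <- -0.102

#' Volume-equivalent sphere radius of an ellipsoid
#'
#' The radius of the sphere with the same volume as an ellipsoid with the
#' given semi-axes, i.e. the geometric mean \eqn{(s_1 s_2 s_3)^{1/3}}. The
#' tubulin dimer (semi-axes 2 x 2.5 x 4 nm) maps to 2.71 nm.
#'
#' @param semi_axes Numeric vector of three positive semi-axes (m).
#' @return Equivalent radius, same units as the input.
#' @export
equivalent_sphere_radius <- function(semi_axes) {
  if (!is.numeric(semi_axes) || length(semi_axes) != 3L || any(semi_axes <= 0))
    .stop_invalid("`semi_axes` must be three positive lengths")
  prod(semi_axes)^(1 / 3)
}

#' Spherical probe particle
#'
#' The repelled particle — in the default scenarios a tubulin dimer modelled
#' as a sphere. Carries both the bare charge and the effective
#' (counterion-corrected) charge actually coupling to the screened field.
#'
#' @param radius Effective sphere radius in m (> 0).
#' @param charge_bare Bare charge in C.
#' @param charge_eff Effective charge in C; `|charge_eff| <= |charge_bare|`.
#' @param mass Particle mass in kg (> 0).
#' @return An object of class `ez_probe` with fields `a`, `Q_bare`, `Q_eff`,
#'   `m`.
#' @seealso [tubulin_probe()], [friction_coefficient()]
#' @export
probe <- function(radius, charge_bare, charge_eff, mass) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    .stop_invalid("`radius` must be a single positive length (m)")
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    .stop_invalid("`mass` must be a single positive mass (kg)")
  stopifnot(is.numeric(charge_bare), is.numeric(charge_eff))
  if (abs(charge_eff) > abs(charge_bare) * (1 + 1e-12))
    .stop_invalid("effective charge cannot exceed the bare charge in magnitude")
  structure(list(a = radius, Q_bare = charge_bare, Q_eff = charge_eff,
                 m = mass),
            class = "ez_probe")
}

#' Effective tubulin-dimer charge at a given salt concentration
#'
#' Counterion condensation partially neutralises the tubulin bare charge of
#' -52 e. The effective charges are tabulated constants: -17 e at 10 mM KCl
#' and -29 e at 160 mM. No interpolation is attempted at other
#' concentrations.
#'
#' @param concentration_mM Either 10 or 160.
#' @return Effective charge in C (negative).
#' @export
tubulin_effective_charge <- function(concentration_mM) {
  charges_e <- c("10" = -17, "160" = -29)
  key <- as.character(concentration_mM)
  if (!key %in% names(charges_e))
    .stop_invalid(paste0(
      "effective tubulin charge is tabulated only at 10 and 160 mM ",
      "(requested %s mM); supply `charge_eff` explicitly for other media"),
      format(concentration_mM))
  unname(charges_e[key]) * .const$e
}

#' Default tubulin-dimer probe
#'
#' A tubulin dimer modelled as a sphere of radius 2.71 nm (volume-equivalent
#' to the 2 x 2.5 x 4 nm ellipsoid), bare charge -52 e, mass 110 kDa, and an
#' effective charge from [tubulin_effective_charge()].
#'
#' @param concentration_mM Salt concentration (10 or 160) selecting the
#'   tabulated effective charge.
#' @return An [probe()] object.
#' @export
tubulin_probe <- function(concentration_mM = 10) {
  probe(radius = equivalent_sphere_radius(c(2, 2.5, 4) * 1e-9),
        charge_bare = -52 * .const$e,
        charge_eff = tubulin_effective_charge(concentration_mM),
        mass = 110000 * .const$dalton)
}

#' Stokes friction coefficient of the probe
#'
#' \eqn{\xi = 6 \pi \eta a}: the drag coefficient of a sphere of radius `a`
#' in a fluid of viscosity `eta` (Stokes approximation, no wall
#' corrections).
#'
#' @param medium An [medium()] object.
#' @param probe An [probe()] object.
#' @return Friction coefficient in kg/s.
#' @export
friction_coefficient <- function(medium, probe) {
  stopifnot(inherits(medium, "ez_medium"), inherits(probe, "ez_probe"))
  6 * pi * medium$eta * probe$a
}

#' Simulation scenario
#'
#' Bundles a charged surface, a medium, a probe, the starting rule and a
#' time horizon into one self-contained simulation case. The probe always
#' starts at rest. Two starting rules are supported:
#' `"stern_contact"` places the probe centre at the Stern boundary
#' (`R + d`, or `d` for the plane) — the innermost coordinate at which the
#' diffuse-layer field is defined, representing a dimer that has just
#' detached; `"probe_contact"` places it one probe radius from the wall
#' (`R + a`, or `a`), representing a dimer resting against the surface.
#'
#' @param surface An [charged_surface()] object.
#' @param medium An [medium()] object.
#' @param probe An [probe()] object.
#' @param start_rule `"stern_contact"` or `"probe_contact"`.
#' @param t_max Time horizon in s (> 0).
#' @return An object of class `ez_scenario`.
#' @examples
#' s <- scenario(charged_surface("plane", sigma = -0.09),
#'               medium(concentration_mM = 10), tubulin_probe(10),
#'               "stern_contact", t_max = 50e-6)
#' start_position(s) * 1e9  # 0.33 nm
#' @export
scenario <- function(surface, medium, probe,
                     start_rule = c("stern_contact", "probe_contact"),
                     t_max = 50e-6) {
  stopifnot(inherits(surface, "ez_surface"), inherits(medium, "ez_medium"),
            inherits(probe, "ez_probe"))
  start_rule <- match.arg(start_rule)
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0)
    .stop_invalid("`t_max` must be a single positive time (s)")
  scn <- structure(
    list(surface = surface, medium = medium, probe = probe,
         start_rule = start_rule, t_max = t_max),
    class = "ez_scenario")
  if (start_position(scn) < stern_boundary(surface))
    .stop_invalid(
      "start position (%.3g m) lies inside the Stern boundary (%.3g m)",
      start_position(scn), stern_boundary(surface))
  scn
}

#' Initial probe coordinate of a scenario
#'
#' @param scenario An [scenario()] object.
#' @return Starting coordinate in m (distance from the axis/centre for
#'   cylinder/sphere, from the wall for the plane).
#' @export
start_position <- function(scenario) {
  stopifnot(inherits(scenario, "ez_scenario"))
  base <- if (scenario$surface$kind == "plane") 0 else scenario$surface$R
  off <- switch(scenario$start_rule,
                stern_contact = scenario$surface$d,
                probe_contact = scenario$probe$a)
  base + off
}

#' @export
print.ez_scenario <- function(x, ...) {
  lam <- debye_length(x$medium)
  cat(sprintf(
    "<ez_scenario> %s | c_s = %g mM (lambda_D = %.3g nm) | sigma = %g C/m^2\n",
    x$surface$kind, x$medium$c_s, lam * 1e9, x$surface$sigma))
  cat(sprintf("  start: %s at %.3g nm, horizon %.3g us, Q_eff = %.1f e\n",
              x$start_rule, start_position(x) * 1e9, x$t_max * 1e6,
              x$probe$Q_eff / .const$e))
  invisible(x)
}
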