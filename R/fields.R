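# Closed-form solutions of the linearized Poisson-Boltzmann (LPB) equation
# outside the Stern layer of a charged cylinder, sphere or plane.
#
# All three geometries share the structure V(x) ~ prefactor * decay(x), with
# the decay set by the Debye length. Ratios of modified Bessel functions are
# evaluated with exponential scaling (besselK(..., expon.scaled = TRUE)) so
# profiles stay finite out to hundreds of Debye lengths; half-integer orders
# use their elementary closed forms K_{1/2}(z) = sqrt(pi/(2z)) e^{-z} and
# K_{3/2}(z) = K_{1/2}(z) (1 + 1/z).

# exponentially scaled half-order Bessel functions: K_nu(x) * e^x
.k12s <- function(x) sqrt(pi / (2 * x))
.k32s <- function(x) .k12s(x) * (1 + 1 / x)

# g(z) * e^{z/lambda}: the (negative) radial derivative of
# z^{-1/2} K_{1/2}(z/lambda), written as the half-order Bessel combination
# of the spherical LPB solution.
.g_scaled <- function(z, lambda) {
  zl <- z / lambda
  z^(-3 / 2) / 2 * .k12s(zl) +
    z^(-1 / 2) / lambda * (.k32s(zl) - lambda / (2 * z) * .k12s(zl))
}

#' Screened-field solution around a charged surface
#'
#' Builds the closed-form linearized Poisson-Boltzmann solution for the
#' electrostatic potential outside the Stern layer of a charged cylinder,
#' sphere or plane immersed in a monovalent electrolyte:
#' \describe{
#'   \item{cylinder}{\eqn{V(r) = \frac{\sigma \lambda_D}{\varepsilon_0
#'     \varepsilon_r} \frac{R}{R+d}
#'     \frac{K_0(r/\lambda_D)}{K_1((R+d)/\lambda_D)}}}
#'   \item{sphere}{the screened (Yukawa-type) solution fixed by the Gauss-law
#'     boundary condition \eqn{-dV/dr = \frac{\sigma}{\varepsilon_0
#'     \varepsilon_r}\frac{R^2}{(R+d)^2}} at \eqn{r = R+d}, expressed through
#'     the half-order Bessel functions \eqn{K_{1/2}, K_{3/2}}}
#'   \item{plane}{\eqn{V(x) = \frac{\sigma \lambda_D}{2 \varepsilon_0
#'     \varepsilon_r} e^{-(x-d)/\lambda_D}}}
#' }
#' with \eqn{\lambda_D} the [debye_length()] of the medium. The solution is
#' defined for coordinates at or beyond the Stern boundary (`R + d`, or `d`
#' for the plane) and decays monotonically to zero.
#'
#' The linearization is formally valid while `|V|` stays below the thermal
#' voltage `k_B T / e` (about 25 mV); when the contact potential exceeds it a
#' message is emitted (the solution is still returned — the linear theory
#' then overestimates the voltage at low salt).
#'
#' @param surface An [charged_surface()] object.
#' @param medium An [medium()] object.
#' @param quiet Suppress the linearization-validity message.
#' @return An object of class `ez_field` with fields `surface`, `medium`,
#'   `lambda_D`; evaluate with [potential()], [efield()], [probe_energy()],
#'   [energy_variation()] and [force()].
#' @examples
#' mt <- charged_surface("cylinder", radius = 12.5e-9, sigma = -0.102)
#' f <- field_solution(mt, medium(concentration_mM = 10), quiet = TRUE)
#' potential(f, 12.83e-9) * 1e3  # contact potential, mV
#' @export
field_solution <- function(surface, medium, quiet = FALSE) {
  stopifnot(inherits(surface, "ez_surface"), inherits(medium, "ez_medium"))
  sol <- structure(
    list(surface = surface, medium = medium, lambda_D = debye_length(medium)),
    class = "ez_field")
  if (!quiet) {
    v0 <- abs(potential(sol, stern_boundary(surface)))
    vt <- .thermal_voltage(medium$T)
    if (v0 > vt)
      message(sprintf(
        paste0("contact potential %.1f mV exceeds the thermal voltage ",
               "%.1f mV; the linearized solution overestimates |V|"),
        v0 * 1e3, vt * 1e3))
  }
  sol
}

.check_domain <- function(solution, coordinate) {
  b <- stern_boundary(solution$surface)
  if (any(coordinate < b * (1 - 1e-12)))
    .stop_invalid(
      "coordinate %.4g m lies inside the Stern boundary (%.4g m)",
      min(coordinate), b)
}

#' Electrostatic potential of a screened-field solution
#'
#' @param solution An [field_solution()] object.
#' @param coordinate Distance from the axis/centre (cylinder, sphere) or
#'   from the wall (plane), in m; vectorised. Must be at or beyond the Stern
#'   boundary.
#' @return Potential in volts, same sign as the surface charge.
#' @export
potential <- function(solution, coordinate) {
  .field_eval(solution, coordinate, what = "V")
}

#' Electric field magnitude along the outward coordinate
#'
#' The (signed) outward field \eqn{E = -dV/dx}. For a negative surface
#' charge the field is negative, and the force on a negative probe charge
#' [force()] is positive (repulsive, pointing away from the surface).
#'
#' @inheritParams potential
#' @return Field in V/m.
#' @export
efield <- function(solution, coordinate) {
  .field_eval(solution, coordinate, what = "E")
}

.field_eval <- function(solution, coordinate, what = c("V", "E")) {
  stopifnot(inherits(solution, "ez_field"), is.numeric(coordinate))
  what <- match.arg(what)
  .check_domain(solution, coordinate)
  s <- solution$surface
  md <- solution$medium
  lam <- solution$lambda_D
  ee <- .const$epsilon_0 * md$epsilon_r
  x <- coordinate
  switch(s$kind,
    cylinder = {
      r0 <- s$R + s$d
      pref <- s$sigma / ee * s$R / r0
      # scaled Bessel ratio: K_nu(x/l) / K_1(r0/l) = Ks_nu(x/l)/Ks_1(r0/l)
      # * exp(-(x - r0)/l); finite for arbitrarily large x/l.
      damp <- exp(-(x - r0) / lam)
      k1b <- besselK(r0 / lam, 1, expon.scaled = TRUE)
      if (what == "V")
        pref * lam * besselK(x / lam, 0, expon.scaled = TRUE) / k1b * damp
      else
        pref * besselK(x / lam, 1, expon.scaled = TRUE) / k1b * damp
    },
    sphere = {
      r0 <- s$R + s$d
      pref <- s$sigma / ee * s$R^2 / r0^2
      damp <- exp(-(x - r0) / lam)
      gb <- .g_scaled(r0, lam)
      if (what == "V")
        pref * x^(-1 / 2) * .k12s(x / lam) * damp / gb
      else
        pref * .g_scaled(x, lam) * damp / gb
    },
    plane = {
      damp <- exp(-(x - s$d) / lam)
      if (what == "V") s$sigma * lam / (2 * ee) * damp
      else s$sigma / (2 * ee) * damp
    })
}

#' Electrostatic energy of a probe charge in the screened field
#'
#' \eqn{U = Q_{eff} V}: the interaction energy of the probe's effective
#' charge with the surface potential. Positive (repulsive) when probe and
#' surface charges share a sign.
#'
#' @inheritParams potential
#' @param charge_eff Effective probe charge in C.
#' @return Energy in joules.
#' @export
probe_energy <- function(solution, coordinate, charge_eff) {
  stopifnot(is.numeric(charge_eff), length(charge_eff) == 1L)
  charge_eff * potential(solution, coordinate)
}

#' Energy variation relative to a starting position
#'
#' \eqn{\Delta U(x) = U(x) - U(x_0)}: the electrostatic energy released by
#' the probe in moving from `start` to `coordinate`. Zero at the start,
#' negative and monotone decreasing outward for repulsive scenarios, tending
#' to \eqn{-U(x_0)} at infinity.
#'
#' @inheritParams probe_energy
#' @param start Starting coordinate in m (same domain as `coordinate`).
#' @return Energy difference in joules, vectorised over `coordinate`.
#' @export
energy_variation <- function(solution, coordinate, start, charge_eff) {
  probe_energy(solution, coordinate, charge_eff) -
    probe_energy(solution, start, charge_eff)
}

#' @export
print.ez_field <- function(x, ...) {
  cat(sprintf(
    "<ez_field> %s LPB solution | lambda_D = %.3g nm | sigma = %g C/m^2\n",
    x$surface$kind, x$lambda_D * 1e9, x$surface$sigma))
  invisible(x)
}

#' Tabulate a field/energy profile
#'
#' Evaluates the potential, field and probe energy on a coordinate grid and
#' returns them in reporting units, ready for CSV export or plotting.
#'
#' @inheritParams probe_energy
#' @param coordinates Coordinate grid in m; defaults to 200 points spanning
#'   the Stern boundary to 10 Debye lengths beyond it.
#' @param start Reference coordinate for the energy-variation column;
#'   defaults to the Stern boundary.
#' @return A data.frame with columns `coordinate_nm`, `relative_distance_nm`,
#'   `V_mV`, `E_V_per_m`, `U_J`, `U_kBT`, `dU_kBT`.
#' @export
field_profile <- function(solution, charge_eff, coordinates = NULL,
                          start = NULL) {
  b <- stern_boundary(solution$surface)
  if (is.null(start)) start <- b
  if (is.null(coordinates))
    coordinates <- seq(b, b + 10 * solution$lambda_D, length.out = 200L)
  V <- potential(solution, coordinates)
  U <- charge_eff * V
  U0 <- probe_energy(solution, start, charge_eff)
  Tm <- solution$medium$T
  data.frame(
    coordinate_nm = coordinates * 1e9,
    relative_distance_nm = (coordinates - start) * 1e9,
    V_mV = V * 1e3,
    E_V_per_m = efield(solution, coordinates),
    U_J = U,
    U_kBT = energy_in_kBT(U, Tm),
    dU_kBT = energy_in_kBT(U - U0, Tm))
}
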