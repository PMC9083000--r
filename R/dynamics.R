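# Deterministic Langevin motion of the repelled probe.
#
# The governing equation is m x''(t) = F(x) - xi x'(t) with F = Q_eff E(x)
# and xi = 6 pi eta a. The inertial relaxation time m/xi is a few
# picoseconds while exclusion-zone growth spans microseconds, so the system
# is extremely stiff; the overdamped first-order reduction x' = F(x)/xi is
# the default integration mode, with the full second-order system available
# for verification. There is no stochastic force: trajectories are
# deterministic and reproducible bit-for-bit.

#' Electrostatic force on the probe
#'
#' \eqn{F = Q_{eff} E(x)}, equal to \eqn{-dU/dx} by construction. Positive
#' (directed away from the surface) when the probe and surface charges share
#' a sign.
#'
#' @inheritParams probe_energy
#' @return Force in newtons, vectorised over `coordinate`.
#' @export
force <- function(solution, coordinate, charge_eff) {
  stopifnot(is.numeric(charge_eff), length(charge_eff) == 1L)
  charge_eff * efield(solution, coordinate)
}

#' Integrate the probe's equation of motion
#'
#' Solves the deterministic Langevin equation
#' \eqn{m \ddot{x} = Q_{eff} E(x) - \xi \dot{x}} from the scenario's start
#' position with zero initial velocity, over `[0, t_max]`.
#'
#' Two modes are provided. `"overdamped"` (default) integrates the
#' first-order reduction \eqn{\dot{x} = F(x)/\xi}, exact up to corrections
#' of order \eqn{m/(\xi t)} — about \eqn{10^{-6}} on microsecond horizons —
#' and reports the velocity as \eqn{F(x)/\xi}. `"full"` integrates the stiff
#' second-order system directly (lsoda switches to a BDF scheme on the fast
#' manifold). Internally positions are scaled to nm and times to
#' microseconds so the tolerances act on well-conditioned quantities.
#'
#' Output is sampled on a logarithmic time grid (plus t = 0): EZ growth is
#' fast at first and logarithmic later, so log spacing resolves both the
#' sub-nanosecond transient and the plateau.
#'
#' @param scenario An [scenario()] object.
#' @param mode `"overdamped"` or `"full"`.
#' @param rtol,atol Relative tolerance, and absolute tolerance on the
#'   position in nm, passed to the integrator.
#' @param n_out Number of output samples after t = 0.
#' @param times Optional explicit output-time grid in s (overrides
#'   `n_out`); must start at 0.
#' @param quiet Suppress the linearization-validity message from the field
#'   construction.
#' @return An object of class `ez_trajectory`: a data.frame with columns
#'   `t` (s), `x` (m), `v` (m/s), plus attributes `scenario` and `solution`.
#' @examples
#' scn <- scenario(charged_surface("plane", sigma = -0.09),
#'                 medium(concentration_mM = 160), tubulin_probe(160),
#'                 "stern_contact", t_max = 1e-6)
#' tr <- integrate_motion(scn, quiet = TRUE)
#' ez_size(tr, 1e-6) * 1e9  # displacement in nm after 1 us
#' @export
integrate_motion <- function(scenario,
                             mode = c("overdamped", "full"),
                             rtol = 1e-8, atol = 1e-12,
                             n_out = 400L, times = NULL, quiet = FALSE) {
  stopifnot(inherits(scenario, "ez_scenario"))
  mode <- match.arg(mode)
  sol <- field_solution(scenario$surface, scenario$medium, quiet = quiet)
  xi <- friction_coefficient(scenario$medium, scenario$probe)
  q <- scenario$probe$Q_eff
  m <- scenario$probe$m
  x0 <- start_position(scenario)

  # internal units: nm for position, us for time -> velocity unit 1e-3 m/s
  u_x <- 1e-9; u_t <- 1e-6; u_v <- u_x / u_t
  if (is.null(times)) {
    tmax_us <- scenario$t_max / u_t
    times_us <- c(0, exp(seq(log(tmax_us * 1e-8), log(tmax_us),
                             length.out = n_out)))
  } else {
    if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
      .stop_invalid("`times` must be strictly increasing and start at 0")
    if (max(times) > scenario$t_max * (1 + 1e-9))
      .stop_invalid("`times` must not exceed the scenario horizon")
    times_us <- times / u_t
  }

  drift_nm_us <- function(x_nm) q * efield(sol, x_nm * u_x) / xi / u_v

  if (mode == "overdamped") {
    rhs <- function(t, y, p) list(drift_nm_us(y[[1]]))
    out <- deSolve::ode(y = c(x = x0 / u_x), times = times_us, func = rhs,
                        method = "lsoda", rtol = rtol, atol = atol)
    .check_solver(out, times_us)
    x <- out[, "x"] * u_x
    v <- q * efield(sol, x) / xi
  } else {
    rhs <- function(t, y, p) {
      a_nm_us2 <- (q * efield(sol, y[[1]] * u_x) - xi * y[[2]] * u_v) *
        u_t / (m * u_v)
      list(c(y[[2]], a_nm_us2))
    }
    out <- deSolve::ode(y = c(x = x0 / u_x, v = 0), times = times_us,
                        func = rhs, method = "lsoda",
                        rtol = rtol, atol = c(atol, atol / u_t))
    .check_solver(out, times_us)
    x <- out[, "x"] * u_x
    v <- out[, "v"] * u_v
  }

  structure(
    data.frame(t = times_us * u_t, x = x, v = v),
    scenario = scenario, solution = sol,
    class = c("ez_trajectory", "data.frame"))
}

.check_solver <- function(out, times_us) {
  if (nrow(out) < length(times_us) || any(!is.finite(out[, -1L])))
    stop(sprintf(
      paste0("ODE integration failed after t = %.3g us ",
             "(%d of %d output points); see diagnostics via ",
             "deSolve::diagnostics"),
      out[nrow(out), 1L], nrow(out), length(times_us)), call. = FALSE)
  invisible(out)
}

#' Exclusion-zone growth profile of a trajectory
#'
#' The EZ size is operationalised as the probe displacement from its start
#' position, `x(t) - x(0)` — the "relative distance" plotted in EZ growth
#' curves — not as a threshold crossing of the potential.
#'
#' @param trajectory An [integrate_motion()] result.
#' @return An object of class `ez_profile`: a data.frame with columns `t`
#'   (s) and `ez` (m), non-decreasing with `ez[1] = 0`.
#' @export
ez_profile <- function(trajectory) {
  stopifnot(inherits(trajectory, "ez_trajectory"))
  structure(
    data.frame(t = trajectory$t, ez = trajectory$x - trajectory$x[1]),
    scenario = attr(trajectory, "scenario"),
    class = c("ez_profile", "data.frame"))
}

#' Exclusion-zone size at a given time
#'
#' Linear interpolation of the displacement profile at `t_eval`.
#'
#' @param trajectory An [integrate_motion()] result.
#' @param t_eval Evaluation time in s, within `[0, max(t)]`.
#' @return Displacement `x(t_eval) - x(0)` in m.
#' @export
ez_size <- function(trajectory, t_eval) {
  stopifnot(inherits(trajectory, "ez_trajectory"),
            is.numeric(t_eval), length(t_eval) == 1L)
  if (t_eval < 0 || t_eval > max(trajectory$t) * (1 + 1e-9))
    .stop_invalid("`t_eval` = %.3g s outside the trajectory range [0, %.3g]",
                  t_eval, max(trajectory$t))
  stats::approx(trajectory$t, trajectory$x - trajectory$x[1],
                xout = t_eval, rule = 2)$y
}

#' Fit an exponential force law to a simulated trajectory
#'
#' Fits \eqn{F(x)/\xi = K e^{-\kappa x}} to the force samples along the
#' trajectory by linear least squares on \eqn{\log(F/\xi)}, the form used to
#' parameterise exclusion-zone growth from time-resolved data. Samples with
#' `F` below `1e-6` of the starting force are dropped to avoid the
#' log-of-zero tail. For the planar geometry the force is exactly
#' exponential, so the fit recovers \eqn{\kappa = 1/\lambda_D} with
#' near-zero residual; for cylinder and sphere the fit captures the
#' quasi-exponential Bessel/Yukawa tail.
#'
#' @param trajectory An [integrate_motion()] result.
#' @return An object of class `ez_force_fit`: a list with `K` (m/s),
#'   `kappa` (1/m), `residual` (root-mean-square residual of the log fit)
#'   and `n` (samples used).
#' @export
fit_force_law <- function(trajectory) {
  stopifnot(inherits(trajectory, "ez_trajectory"))
  scn <- attr(trajectory, "scenario")
  sol <- attr(trajectory, "solution")
  xi <- friction_coefficient(scn$medium, scn$probe)
  Fx <- force(sol, trajectory$x, scn$probe$Q_eff)
  keep <- Fx > 1e-6 * Fx[1] & Fx > 0
  # collapse the repeated start coordinate and the converged tail
  keep <- keep & !duplicated(trajectory$x)
  if (sum(keep) < 10L)
    .stop_invalid(
      "trajectory has %d usable force samples (need >= 10); no motion to fit",
      sum(keep))
  x <- trajectory$x[keep]
  y <- log(Fx[keep] / xi)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(
    list(K = exp(unname(co[1])), kappa = -unname(co[2]),
         residual = sqrt(mean(stats::residuals(fit)^2)), n = sum(keep)),
    class = "ez_force_fit")
}

#' @export
print.ez_force_fit <- function(x, ...) {
  cat(sprintf(
    "<ez_force_fit> F/xi = K exp(-kappa x): K = %.4g m/s, 1/kappa = %.3g nm, rms(log) = %.2g (n = %d)\n",
    x$K, 1e9 / x$kappa, x$residual, x$n))
  invisible(x)
}

#' Time to reach a fraction of the final displacement
#'
#' @param trajectory An [integrate_motion()] result.
#' @param fraction Fraction of the displacement at the trajectory horizon
#'   (default 0.9).
#' @return Time in s (linear interpolation).
#' @export
time_to_fraction <- function(trajectory, fraction = 0.9) {
  stopifnot(fraction > 0, fraction < 1)
  ez <- trajectory$x - trajectory$x[1]
  target <- fraction * ez[length(ez)]
  if (target <= 0) return(0)
  i <- which(ez >= target)[1]
  if (i == 1L) return(trajectory$t[1])
  stats::approx(ez[c(i - 1L, i)], trajectory$t[c(i - 1L, i)],
                xout = target)$y
}
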