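# Independent oracles used across test files. Each recomputes a quantity by
# a route separate from the implementation: numerical quadrature for the
# Bessel functions, the analytically derived Yukawa form for the sphere,
# central finite differences for fields, closed-form quadrature for the
# planar overdamped motion.

# Modified Bessel function of the second kind via its integral
# representation K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt,
# independent of base::besselK.
bessel_k_quad <- function(x, nu) {
  vapply(x, function(xx) {
    stats::integrate(function(t) exp(-xx * cosh(t)) * cosh(nu * t),
                     0, 30, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Independently entered CODATA constants (typed separately from R/constants.R)
ORACLE_E <- 1.602176634e-19
ORACLE_NA <- 6.02214076e23
ORACLE_KB <- 1.380649e-23
ORACLE_EPS0 <- 8.8541878128e-12

# Brute-force Debye length from first principles, c_s in mol/m^3
debye_length_oracle <- function(epsilon_r, temperature, c_s) {
  num <- ORACLE_EPS0 * epsilon_r * ORACLE_KB * temperature
  den <- 2 * ORACLE_NA * c_s * ORACLE_E^2
  sqrt(num / den)
}

# Screened-sphere (Yukawa) potential derived analytically from the
# Gauss-law boundary condition -dV/dr = sigma/(eps0 epsr) R^2/(R+d)^2 at
# r0 = R + d applied to V = A exp(-r/lambda)/r.
yukawa_sphere_V <- function(r, R, d, sigma, epsilon_r, lambda) {
  r0 <- R + d
  E0 <- sigma / (ORACLE_EPS0 * epsilon_r) * R^2 / r0^2
  A_scaled <- E0 * r0^2 * lambda / (r0 + lambda)  # A * exp(-r0/lambda)
  A_scaled * exp(-(r - r0) / lambda) / r
}

yukawa_sphere_E <- function(r, R, d, sigma, epsilon_r, lambda) {
  yukawa_sphere_V(r, R, d, sigma, epsilon_r, lambda) * (1 / lambda + 1 / r)
}

# Central-difference -dV/dx check of the field on a log-spaced grid.
# Returns the max relative deviation between efield() and -dV/dx.
fd_field_deviation <- function(solution, n = 50, span = 8) {
  b <- stern_boundary(solution$surface)
  lam <- solution$lambda_D
  r <- b + lam * exp(seq(log(1e-3), log(span), length.out = n))
  h <- pmax(r * 1e-7, 1e-15)
  dV <- (potential(solution, r + h) - potential(solution, r - h)) / (2 * h)
  max(abs((-dV - efield(solution, r)) / efield(solution, r)))
}

# Exact overdamped trajectory for the planar geometry:
# dx/dt = B exp(-(x - d)/lambda)  =>
# exp((x - d)/lambda) = exp((x0 - d)/lambda) + B t / lambda
plane_overdamped_x <- function(t, x0, d, lambda, B) {
  d + lambda * log(exp((x0 - d) / lambda) + B * t / lambda)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Cached run of the twelve default scenarios (shared across test files).
.ez_cache <- new.env(parent = emptyenv())
default_results <- function() {
  if (is.null(.ez_cache$res)) {
    .ez_cache$res <- suppressMessages(
      run_scenarios(tubulin_scenarios(), quiet = TRUE))
  }
  .ez_cache$res
}
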