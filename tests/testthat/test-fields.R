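md10 <- medium(concentration_mM = 10)
md160 <- medium(concentration_mM = 160)
mt <- charged_surface("cylinder", radius = 12.5e-9, sigma = -0.102)
tub <- charged_surface("sphere", radius = 2.71e-9, sigma = -0.090)
sheet <- charged_surface("plane", sigma = -0.090)

test_that("cylindrical potential matches a term-by-term evaluation with quadrature Bessel functions", {
  sol <- field_solution(mt, md10, quiet = TRUE)
  lam <- sol$lambda_D
  r0 <- 12.5e-9 + 0.33e-9
  for (r in c(r0, r0 + lam, r0 + 5 * lam)) {
    expected <- -0.102 * lam / (ORACLE_EPS0 * 78.3) * (12.5 / 12.83) *
      bessel_k_quad(r / lam, 0) / bessel_k_quad(r0 / lam, 1)
    expect_equal(potential(sol, r), expected, tolerance = 1e-8)
  }
  # field at contact reduces to sigma/(eps0 epsr) * R/(R+d): Bessel ratio 1
  expect_equal(efield(sol, r0),
               -0.102 / (ORACLE_EPS0 * 78.3) * 12.5 / 12.83,
               tolerance = 1e-12)
})

test_that("E = -dV/dx holds for all three geometries (central differences)", {
  for (surf in list(mt, tub, sheet)) {
    for (md in list(md10, md160)) {
      sol <- field_solution(surf, md, quiet = TRUE)
      expect_lt(fd_field_deviation(sol), 1e-6)
    }
  }
})

test_that("spherical solution equals the analytically derived Yukawa form", {
  for (md in list(md10, md160)) {
    sol <- field_solution(tub, md, quiet = TRUE)
    lam <- sol$lambda_D
    r0 <- 2.71e-9 + 0.33e-9
    r <- seq(r0, r0 + 20 * lam, length.out = 200)
    expect_equal(potential(sol, r),
                 yukawa_sphere_V(r, 2.71e-9, 0.33e-9, -0.090, 78.3, lam),
                 tolerance = 1e-10)
    expect_equal(efield(sol, r),
                 yukawa_sphere_E(r, 2.71e-9, 0.33e-9, -0.090, 78.3, lam),
                 tolerance = 1e-10)
    # Gauss-law boundary condition at the Stern surface
    expect_equal(efield(sol, r0),
                 -0.090 / (ORACLE_EPS0 * 78.3) * (2.71 / 3.04)^2,
                 tolerance = 1e-10)
  }
})

test_that("planar solution has the exact exponential identities", {
  sol <- field_solution(sheet, md10, quiet = TRUE)
  lam <- sol$lambda_D
  d <- 0.33e-9
  expect_equal(potential(sol, d), -0.090 * lam / (2 * ORACLE_EPS0 * 78.3),
               tolerance = 1e-12)
  expect_equal(potential(sol, d + lam) / potential(sol, d), exp(-1),
               tolerance = 1e-12)
  x <- d + lam * seq(0, 10, length.out = 50)
  expect_equal(efield(sol, x), potential(sol, x) / lam, tolerance = 1e-12)
})

test_that("potentials decay monotonically, vanish far away, and carry the sign of sigma", {
  for (surf in list(mt, tub, sheet)) {
    sol <- field_solution(surf, md10, quiet = TRUE)
    b <- stern_boundary(surf)
    lam <- sol$lambda_D
    r <- b + lam * seq(0, 20, length.out = 100)
    V <- potential(sol, r)
    E <- efield(sol, r)
    expect_true(all(V < 0))            # sign(V) = sign(sigma)
    expect_true(all(diff(abs(V)) < 0)) # strict decay
    expect_true(all(diff(abs(E)) < 0))
    expect_lt(abs(V[100] / V[1]), exp(-19)) # screened to ~e^-20 at 20 lambda
    # stronger screening at higher salt; the contact field itself is set by
    # the Gauss boundary condition and is salt-independent, so compare
    # strictly beyond the boundary
    sol_hi <- field_solution(surf, md160, quiet = TRUE)
    expect_true(all(abs(potential(sol_hi, r)) < abs(V)))
    expect_true(all(abs(efield(sol_hi, r[-1])) < abs(E[-1])))
  }
})

test_that("far-field evaluation stays finite out to hundreds of Debye lengths", {
  for (surf in list(mt, tub, sheet)) {
    sol <- field_solution(surf, md10, quiet = TRUE)
    r <- stern_boundary(surf) + sol$lambda_D * c(100, 400, 700)
    expect_true(all(is.finite(potential(sol, r))))
    expect_true(all(is.finite(efield(sol, r))))
    expect_true(all(abs(potential(sol, r)) >= 0))
  }
})

test_that("coordinates inside the Stern layer are rejected", {
  sol <- field_solution(mt, md10, quiet = TRUE)
  expect_error(potential(sol, 12.5e-9), "Stern")
  expect_error(efield(sol, 0), "Stern")
  solp <- field_solution(sheet, md10, quiet = TRUE)
  expect_error(potential(solp, 0.1e-9), "Stern")
})

test_that("probe energy is Q_eff * V, repulsive for like charges, hundreds of kBT at contact", {
  sol <- field_solution(mt, md10, quiet = TRUE)
  q <- tubulin_effective_charge(10)
  r0 <- stern_boundary(mt)
  r <- r0 + sol$lambda_D * seq(0, 10, length.out = 20)
  expect_equal(probe_energy(sol, r, q), q * potential(sol, r))
  expect_true(all(probe_energy(sol, r, q) > 0))  # like charges repel
  expect_identical(probe_energy(sol, r, 0), rep(0, length(r)))
  U0 <- energy_in_kBT(probe_energy(sol, r0, q), 293.15)
  expect_gt(U0, 100)   # hundreds of kBT at Stern contact
  expect_lt(U0, 1000)
})

test_that("energy variation is zero at the start and tends to -U(start)", {
  sol <- field_solution(tub, md10, quiet = TRUE)
  q <- tubulin_effective_charge(10)
  r0 <- stern_boundary(tub)
  expect_equal(energy_variation(sol, r0, r0, q), 0)
  r <- r0 + sol$lambda_D * seq(0, 30, length.out = 60)
  dU <- energy_variation(sol, r, r0, q)
  expect_true(all(diff(dU) < 0))  # monotone decreasing outward
  expect_equal(dU[60], -probe_energy(sol, r0, q), tolerance = 1e-10)
})

test_that("linearization-validity message fires when |V| exceeds the thermal voltage", {
  expect_message(field_solution(mt, md10), "thermal voltage")
  # a weakly charged surface stays linear and silent
  weak <- charged_surface("plane", sigma = -0.001)
  expect_silent(field_solution(weak, md160))
})

test_that("field_profile tabulates reporting units consistently", {
  sol <- field_solution(sheet, md160, quiet = TRUE)
  q <- tubulin_effective_charge(160)
  prof <- field_profile(sol, q)
  expect_named(prof, c("coordinate_nm", "relative_distance_nm", "V_mV",
                       "E_V_per_m", "U_J", "U_kBT", "dU_kBT"))
  expect_equal(prof$dU_kBT[1], 0)
  expect_equal(prof$U_kBT, energy_in_kBT(prof$U_J, 293.15))
  expect_equal(prof$relative_distance_nm,
               prof$coordinate_nm - prof$coordinate_nm[1])
})
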