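make_scn <- function(kind = "cylinder", c_mM = 10, rule = "stern_contact",
                     t_max = 50e-6) {
  tubulin_scenarios(t_max)[[sprintf("%s_%gmM_%s", kind, c_mM, rule)]]
}

test_that("force is Q_eff E, repulsive for like charges, and equals -dU/dx", {
  scn <- make_scn()
  sol <- field_solution(scn$surface, scn$medium, quiet = TRUE)
  q <- scn$probe$Q_eff
  r0 <- stern_boundary(scn$surface)
  r <- r0 + sol$lambda_D * exp(seq(log(0.01), log(8), length.out = 40))
  expect_true(all(force(sol, r, q) > 0))   # sigma < 0, Q_eff < 0 -> repulsion
  expect_identical(force(sol, r, 0), rep(0, length(r)))
  h <- r * 1e-7
  dU <- (probe_energy(sol, r + h, q) - probe_energy(sol, r - h, q)) / (2 * h)
  expect_equal(force(sol, r, q), -dU, tolerance = 1e-6)
})

test_that("an uncharged probe does not move", {
  scn <- make_scn(t_max = 1e-6)
  scn$probe$Q_eff <- 0
  tr <- integrate_motion(scn, quiet = TRUE)
  expect_true(all(tr$x == tr$x[1]))
  expect_true(all(tr$v == 0))
  tr2 <- integrate_motion(scn, mode = "full", quiet = TRUE)
  expect_true(all(abs(tr2$x - tr2$x[1]) < 1e-15))
})

test_that("overdamped planar motion matches the closed-form quadrature solution", {
  for (c_mM in c(10, 160)) {
    scn <- make_scn("plane", c_mM, t_max = 20e-6)
    tr <- integrate_motion(scn, quiet = TRUE)
    lam <- debye_length(scn$medium)
    xi <- friction_coefficient(scn$medium, scn$probe)
    B <- scn$probe$Q_eff * scn$surface$sigma /
      (2 * ORACLE_EPS0 * scn$medium$epsilon_r * xi)
    x_exact <- plane_overdamped_x(tr$t, start_position(scn), scn$surface$d,
                                  lam, B)
    expect_equal(tr$x, x_exact, tolerance = 1e-7)
  }
})

test_that("trajectories start at rest, never retreat, and decelerate to a plateau", {
  for (kind in c("cylinder", "sphere", "plane")) {
    scn <- make_scn(kind, t_max = 20e-6)
    tr <- integrate_motion(scn, quiet = TRUE)
    expect_equal(tr$x[1], start_position(scn))
    expect_true(all(diff(tr$x) >= 0))          # repulsion only: monotone
    expect_true(all(tr$v >= 0))
    expect_lt(tr$v[nrow(tr)], tr$v[1] * 1e-3)  # force has died down
  }
})

test_that("full second-order integration agrees with the overdamped reduction after the inertial transient", {
  scn <- make_scn(t_max = 5e-6)
  tr_o <- integrate_motion(scn, quiet = TRUE)
  tr_f <- integrate_motion(scn, mode = "full", quiet = TRUE)
  expect_equal(tr_f$t, tr_o$t)
  # the inertial time m/xi is ~3.6 ps; beyond ~1 ns the displacement
  # deficit v0 m/xi is <1% of the displacement itself
  sel <- tr_o$t > 1e-9
  d_o <- tr_o$x[sel] - tr_o$x[1]
  d_f <- tr_f$x[sel] - tr_f$x[1]
  expect_lt(max(abs(d_f - d_o) / d_o), 0.01)
})

test_that("energy bookkeeping closes: friction work equals electrostatic energy released", {
  scn <- make_scn(t_max = 10e-6)
  tr <- integrate_motion(scn, n_out = 2000, quiet = TRUE)
  sol <- attr(tr, "solution")
  xi <- friction_coefficient(scn$medium, scn$probe)
  W_friction <- trapz(tr$x, xi * tr$v)
  dU <- probe_energy(sol, tr$x[1], scn$probe$Q_eff) -
    probe_energy(sol, tr$x[nrow(tr)], scn$probe$Q_eff)
  kinetic <- 0.5 * scn$probe$m * tr$v[nrow(tr)]^2
  expect_equal(W_friction + kinetic, dU, tolerance = 1e-3)
})

test_that("ez_size interpolates the displacement and is monotone in time", {
  scn <- make_scn(t_max = 10e-6)
  tr <- integrate_motion(scn, quiet = TRUE)
  expect_equal(ez_size(tr, 0), 0)
  ts <- c(1e-8, 1e-7, 1e-6, 5e-6, 10e-6)
  ez <- vapply(ts, function(t) ez_size(tr, t), numeric(1))
  expect_true(all(diff(ez) > 0))
  expect_equal(ez[5], tr$x[nrow(tr)] - tr$x[1], tolerance = 1e-9)
  expect_error(ez_size(tr, 11e-6), "range")
  expect_error(ez_size(tr, -1), "range")
  prof <- ez_profile(tr)
  expect_equal(prof$ez[1], 0)
  expect_true(all(diff(prof$ez) >= 0))
})

test_that("exclusion zone shrinks with salt and grows on a microsecond timescale", {
  res <- default_results()
  smry <- summary_table(res)
  for (kind in c("cylinder", "sphere", "plane")) {
    for (rule in c("stern_contact", "probe_contact")) {
      lo <- smry[smry$geometry == kind & smry$c_mM == 10 &
                   smry$start_rule == rule, ]
      hi <- smry[smry$geometry == kind & smry$c_mM == 160 &
                   smry$start_rule == rule, ]
      expect_lt(hi$ez_horizon_nm, lo$ez_horizon_nm)
      expect_lt(hi$ez_10us_nm, lo$ez_10us_nm)
    }
  }
  # time to 90% of the 50 us displacement sits in the us - tens of us band
  expect_true(all(smry$t90_us > 1 & smry$t90_us < 50))
})

test_that("start rule has little effect on EZ growth at low salt on microsecond timescales", {
  res <- default_results()
  for (kind in c("cylinder", "sphere", "plane")) {
    a <- res[[sprintf("%s_10mM_stern_contact", kind)]]$trajectory
    b <- res[[sprintf("%s_10mM_probe_contact", kind)]]$trajectory
    sel <- a$t >= 1e-6
    da <- a$x[sel] - a$x[1]
    db <- b$x[sel] - b$x[1]
    expect_lt(max(abs(da - db) / pmax(da, db)), 0.15)
    # at high salt the curves keep a constant offset on the scale of the
    # start-position gap (a - d), but no more
    a2 <- res[[sprintf("%s_160mM_stern_contact", kind)]]$trajectory
    b2 <- res[[sprintf("%s_160mM_probe_contact", kind)]]$trajectory
    gap <- abs((a2$x[nrow(a2)] - a2$x[1]) - (b2$x[nrow(b2)] - b2$x[1]))
    expect_lt(gap, 2.71e-9 - 0.33e-9 + debye_length(medium(concentration_mM = 160)))
  }
})

test_that("force-law fit is exact for the planar geometry", {
  scn <- make_scn("plane", 10)
  tr <- integrate_motion(scn, quiet = TRUE)
  fit <- fit_force_law(tr)
  lam <- debye_length(scn$medium)
  xi <- friction_coefficient(scn$medium, scn$probe)
  expect_equal(fit$kappa, 1 / lam, tolerance = 1e-3)
  expect_lt(fit$residual, 1e-8)
  # closed-form amplitude K = |Q_eff sigma / (2 eps0 epsr xi)| e^{d/lambda}
  K_expected <- abs(scn$probe$Q_eff * scn$surface$sigma /
                      (2 * ORACLE_EPS0 * scn$medium$epsilon_r * xi)) *
    exp(scn$surface$d / lam)
  expect_equal(fit$K, K_expected, tolerance = 1e-3)
})

test_that("fitted exponential tracks the cylindrical force over the near field", {
  scn <- make_scn("cylinder", 10)
  tr <- integrate_motion(scn, quiet = TRUE)
  fit <- fit_force_law(tr)
  expect_gt(fit$K, 0)
  expect_gt(fit$kappa, 0)
  sol <- attr(tr, "solution")
  xi <- friction_coefficient(scn$medium, scn$probe)
  x <- seq(tr$x[1], tr$x[1] + 5 * sol$lambda_D, length.out = 100)
  predicted <- xi * fit$K * exp(-fit$kappa * x)
  expect_lt(max(abs(predicted / force(sol, x, scn$probe$Q_eff) - 1)), 0.10)
})

test_that("degenerate trajectories cannot be fitted", {
  scn <- make_scn(t_max = 1e-6)
  scn$probe$Q_eff <- 0
  tr <- integrate_motion(scn, quiet = TRUE)
  expect_error(fit_force_law(tr), "no motion")
})

test_that("explicit output grids are validated", {
  scn <- make_scn(t_max = 1e-6)
  tr <- integrate_motion(scn, times = c(0, 1e-8, 1e-7, 1e-6), quiet = TRUE)
  expect_equal(tr$t, c(0, 1e-8, 1e-7, 1e-6))
  expect_error(integrate_motion(scn, times = c(1e-8, 1e-7), quiet = TRUE),
               "start at 0")
  expect_error(integrate_motion(scn, times = c(0, 2e-6), quiet = TRUE),
               "horizon")
})
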