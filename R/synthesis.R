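# Randomized-but-physical scenario generation for property testing.
#
# Samples parameter sets bracketing (and exceeding) the default tubulin
# regime so every stage of the pipeline can be exercised without external
# data. Concentration and surface-charge magnitude span decades and are
# sampled log-uniformly; the remaining parameters are sampled uniformly.

#' Parameter space for randomized scenario generation
#'
#' Defines the sampling ranges. Defaults bracket the tubulin regime:
#' 1-500 mM salt, surface charge -0.2 to -0.01 C/m^2, body radius 1-50 nm,
#' probe radius 1-10 nm, effective charge -50 to -1 e, temperature
#' 273-320 K, viscosity 0.3-3 mPa s, relative permittivity 40-90.
#'
#' @param c_s_mM,sigma,R_nm,a_nm,Q_eff_e,T_K,eta_Pa_s,epsilon_r Length-two
#'   numeric ranges (min, max). `sigma` and `Q_eff_e` are negative;
#'   their magnitudes are sampled log-uniformly (as is `c_s_mM`).
#' @param t_max Horizon in s given to every sampled scenario.
#' @return An object of class `ez_parameter_space`.
#' @export
parameter_space <- function(c_s_mM = c(1, 500),
                            sigma = c(-0.2, -0.01),
                            R_nm = c(1, 50),
                            a_nm = c(1, 10),
                            Q_eff_e = c(-50, -1),
                            T_K = c(273, 320),
                            eta_Pa_s = c(0.3e-3, 3e-3),
                            epsilon_r = c(40, 90),
                            t_max = 10e-6) {
  ranges <- list(c_s_mM = c_s_mM, sigma = sigma, R_nm = R_nm, a_nm = a_nm,
                 Q_eff_e = Q_eff_e, T_K = T_K, eta_Pa_s = eta_Pa_s,
                 epsilon_r = epsilon_r)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || r[1] >= r[2])
      .stop_invalid("`%s` must be an increasing (min, max) pair", nm)
  }
  if (sigma[2] >= 0 || Q_eff_e[2] >= 0)
    .stop_invalid("`sigma` and `Q_eff_e` ranges must be strictly negative")
  structure(c(ranges, list(t_max = t_max)), class = "ez_parameter_space")
}

.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Sample randomized physical scenarios
#'
#' Draws `n` scenarios from a [parameter_space()], reproducibly from `seed`.
#' Geometry kind and start rule are sampled uniformly; concentration and
#' surface-charge magnitude log-uniformly; everything else uniformly. Every
#' sampled scenario passes the full type validation (the probe bare charge
#' is fixed at -52 e, which bounds all sampled effective charges). The
#' caller's RNG state is left untouched.
#'
#' @param space An [parameter_space()] object.
#' @param n Number of scenarios (> 0).
#' @param seed Integer seed governing all sampling.
#' @return A named list of `n` [scenario()] objects.
#' @export
sample_scenarios <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "ez_parameter_space"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    .stop_invalid("`n` must be a positive count")
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  kind <- sample(c("cylinder", "sphere", "plane"), n, replace = TRUE)
  rule <- sample(c("stern_contact", "probe_contact"), n, replace = TRUE)
  c_mM <- .runif_log(n, space$c_s_mM[1], space$c_s_mM[2])
  sig <- -.runif_log(n, -space$sigma[2], -space$sigma[1])
  R <- stats::runif(n, space$R_nm[1], space$R_nm[2]) * 1e-9
  a <- stats::runif(n, space$a_nm[1], space$a_nm[2]) * 1e-9
  qe <- stats::runif(n, space$Q_eff_e[1], space$Q_eff_e[2]) * .const$e
  Tk <- stats::runif(n, space$T_K[1], space$T_K[2])
  eta <- stats::runif(n, space$eta_Pa_s[1], space$eta_Pa_s[2])
  er <- stats::runif(n, space$epsilon_r[1], space$epsilon_r[2])

  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- scenario(
      surface = charged_surface(kind[i],
                                radius = if (kind[i] == "plane") NULL else R[i],
                                stern = 0.33e-9, sigma = sig[i]),
      medium = medium(epsilon_r = er[i], temperature = Tk[i],
                      viscosity = eta[i], concentration_mM = c_mM[i]),
      probe = probe(radius = a[i], charge_bare = -52 * .const$e,
                    charge_eff = qe[i], mass = 110000 * .const$dalton),
      start_rule = rule[i], t_max = space$t_max)
  }
  names(out) <- sprintf("synth_%03d_%s_%.3gmM", seq_len(n), kind, c_mM)
  out
}

#' Reference checks for the default tubulin scenarios
#'
#' Pairs the default scenarios (and two medium-level quantities) with the
#' expected values and tolerances of the canonical results: the Debye
#' lengths at 10 and 160 mM, the microtubule EZ of about 30 nm at 10 mM,
#' the tubulin-tubulin EZ of about 20 nm at 10 us, and the sheet-to-
#' microtubule energy-variation ratio of about one half. Used by the
#' regression/acceptance tests; [run_scenarios()] on [tubulin_scenarios()]
#' produces everything needed to evaluate them.
#'
#' @return A data.frame with columns `check`, `scenario_id`, `quantity`,
#'   `expected`, `rel_tol`. Quantities: `debye_length_nm`,
#'   `ez_horizon_nm` (horizon 50 us), `ez_10us_nm`, `dU_ratio_vs` (ratio of
#'   `dU_total_kBT` against the scenario named in `scenario_id2`).
#' @export
reference_checks <- function() {
  df <- data.frame(
    check = c("debye_10mM", "debye_160mM", "mt_ez_10mM", "sphere_ez_10us",
              "sheet_vs_mt_energy"),
    scenario_id = c(NA, NA, "cylinder_10mM_stern_contact",
                    "sphere_10mM_stern_contact",
                    "plane_10mM_stern_contact"),
    quantity = c("debye_length_nm", "debye_length_nm", "ez_horizon_nm",
                 "ez_10us_nm", "dU_ratio_vs"),
    expected = c(3, 0.75, 30, 20, 0.5),
    rel_tol = c(0.05, 0.05, 0.20, 0.20, 0.25),
    stringsAsFactors = FALSE)
  df$scenario_id2 <- c(NA, NA, NA, NA, "cylinder_10mM_stern_contact")
  df
}
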