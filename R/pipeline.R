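# Scenario runner: builds the twelve default tubulin scenarios
# (3 geometries x 2 KCl concentrations x 2 start rules), integrates each,
# and tabulates EZ growth, energy-variation profiles and summary numbers.

.default_conditions <- function() {
  list(
    cylinder = list(radius = 12.5e-9, sigma = mt_sigma_default),
    sphere   = list(radius = 2.71e-9, sigma = -0.090),
    plane    = list(radius = NULL,    sigma = -0.090))
}

#' The twelve default tubulin scenarios
#'
#' Builds the full factorial of geometry (microtubule cylinder, tubulin
#' sphere, tubulin sheet) by KCl concentration (10, 160 mM) by start rule
#' (Stern contact, probe contact), with the canonical parameters: cylinder
#' R = 12.5 nm with sigma = -0.102 C/m^2; sphere R = 2.71 nm and plane,
#' both with sigma = -0.090 C/m^2; Stern layer 0.33 nm; tubulin probe
#' (a = 2.71 nm, Q_bare = -52 e, m = 110 kDa) with effective charge -17 e
#' at 10 mM and -29 e at 160 mM; water at 20 degrees C (eta = 1e-3 Pa s,
#' epsilon_r = 78.3).
#'
#' @param t_max Time horizon in s applied to every scenario (default 50 us).
#' @return A named list of 12 [scenario()] objects; names look like
#'   `"cylinder_10mM_stern_contact"`.
#' @export
tubulin_scenarios <- function(t_max = 50e-6) {
  geo <- .default_conditions()
  out <- list()
  for (kind in names(geo)) {
    for (c_mM in c(10, 160)) {
      for (rule in c("stern_contact", "probe_contact")) {
        id <- sprintf("%s_%gmM_%s", kind, c_mM, rule)
        out[[id]] <- scenario(
          surface = charged_surface(kind, radius = geo[[kind]]$radius,
                                    stern = 0.33e-9,
                                    sigma = geo[[kind]]$sigma),
          medium = medium(concentration_mM = c_mM),
          probe = tubulin_probe(c_mM),
          start_rule = rule, t_max = t_max)
      }
    }
  }
  out
}

#' Run a single scenario end to end
#'
#' Integrates the motion, extracts the EZ growth profile, tabulates the
#' energy variation along the visited coordinates (so the EZ-vs-time and
#' energy-vs-distance tables share support), fits the exponential force law
#' and collects summary numbers. Deterministic: identical inputs yield
#' identical output, bit for bit.
#'
#' Each run logs the Debye length, friction coefficient and contact
#' potential, with a note when the contact potential exceeds the ~25 mV
#' thermal voltage (where the linearized field overestimates `|V|`).
#'
#' @param scenario An [scenario()] object.
#' @param id Optional scenario label carried into the summary.
#' @param mode,rtol,atol,n_out Passed to [integrate_motion()].
#' @param quiet Suppress the per-scenario log messages.
#' @return An object of class `ez_result`: a list with elements `id`,
#'   `scenario`, `trajectory`, `ez` ([ez_profile()]), `energy` (data.frame
#'   `relative_distance_nm`, `dU_J`, `dU_kBT`, ...), `fit`
#'   ([fit_force_law()]) and `summary` (list with `ez_at_horizon_m`,
#'   `ez_at_10us_m`, `dU_total_kBT`, `time_to_90pct_s`).
#' @export
run_scenario <- function(scenario, id = NULL, mode = "overdamped",
                         rtol = 1e-8, atol = 1e-12, n_out = 400L,
                         quiet = FALSE) {
  stopifnot(inherits(scenario, "ez_scenario"))
  sol <- field_solution(scenario$surface, scenario$medium, quiet = TRUE)
  if (!quiet) {
    v0 <- potential(sol, stern_boundary(scenario$surface))
    message(sprintf(
      "[%s] lambda_D = %.3g nm, xi = %.3g kg/s, contact V = %.1f mV%s",
      if (is.null(id)) scenario$surface$kind else id,
      sol$lambda_D * 1e9,
      friction_coefficient(scenario$medium, scenario$probe),
      v0 * 1e3,
      if (abs(v0) > .thermal_voltage(scenario$medium$T))
        " (exceeds the thermal voltage; linearization overestimates |V|)"
      else ""))
  }
  traj <- integrate_motion(scenario, mode = mode, rtol = rtol, atol = atol,
                           n_out = n_out, quiet = TRUE)
  ez <- ez_profile(traj)
  q <- scenario$probe$Q_eff
  Tm <- scenario$medium$T
  dU <- energy_variation(sol, traj$x, traj$x[1], q)
  energy <- data.frame(
    coordinate_nm = traj$x * 1e9,
    relative_distance_nm = (traj$x - traj$x[1]) * 1e9,
    V_mV = potential(sol, traj$x) * 1e3,
    E_V_per_m = efield(sol, traj$x),
    U_J = probe_energy(sol, traj$x, q),
    U_kBT = energy_in_kBT(probe_energy(sol, traj$x, q), Tm),
    dU_kBT = energy_in_kBT(dU, Tm))
  fit <- fit_force_law(traj)
  horizon <- max(traj$t)
  summary <- list(
    ez_at_horizon_m = ez_size(traj, horizon),
    ez_at_10us_m = if (horizon >= 10e-6) ez_size(traj, 10e-6) else NA_real_,
    dU_total_kBT = energy_in_kBT(dU[length(dU)], Tm),
    time_to_90pct_s = time_to_fraction(traj, 0.9))
  structure(
    list(id = id %||% scenario$surface$kind, scenario = scenario,
         trajectory = traj, ez = ez, energy = energy, fit = fit,
         summary = summary),
    class = "ez_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ez_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ez_result> %s\n", x$id))
  cat(sprintf(
    "  EZ at horizon: %.3g nm | EZ at 10 us: %s nm | dU: %.3g kBT | t90: %.3g us\n",
    s$ez_at_horizon_m * 1e9,
    if (is.na(s$ez_at_10us_m)) "NA" else sprintf("%.3g", s$ez_at_10us_m * 1e9),
    s$dU_total_kBT, s$time_to_90pct_s * 1e6))
  invisible(x)
}

#' Run a collection of scenarios
#'
#' Runs each scenario in turn; failures are caught, reported and recorded so
#' the remaining scenarios still run.
#'
#' @param scenarios Named list of [scenario()] objects, e.g. from
#'   [tubulin_scenarios()] or [read_scenario_config()].
#' @param output_dir Optional directory: per-scenario trajectory and energy
#'   CSVs plus a combined `summary.csv` are written there.
#' @param ... Passed to [run_scenario()].
#' @return An object of class `ez_result_set`: a named list of `ez_result`
#'   (or `try-error` for failed scenarios), with the summary table available
#'   via [summary_table()].
#' @export
run_scenarios <- function(scenarios, output_dir = NULL, ...) {
  stopifnot(is.list(scenarios), length(scenarios) > 0)
  ids <- names(scenarios) %||% as.character(seq_along(scenarios))
  results <- vector("list", length(scenarios))
  names(results) <- ids
  for (i in seq_along(scenarios)) {
    results[[i]] <- tryCatch(
      run_scenario(scenarios[[i]], id = ids[i], ...),
      error = function(e) {
        warning(sprintf("scenario '%s' failed: %s", ids[i], conditionMessage(e)),
                call. = FALSE)
        structure(conditionMessage(e), class = "ez_failed")
      })
  }
  results <- structure(results, class = "ez_result_set")
  if (!is.null(output_dir)) write_results(results, output_dir)
  results
}

#' Summary table of a result set
#'
#' One row per scenario: EZ at the horizon and at 10 us (both always
#' reported so curves evaluated at either horizon can be compared), total
#' energy released, time to 90% of the final displacement, and the fitted
#' exponential force-law parameters.
#'
#' @param results An [run_scenarios()] result set.
#' @return A data.frame with columns `id`, `geometry`, `c_mM`, `start_rule`,
#'   `lambda_D_nm`, `ez_horizon_nm`, `ez_10us_nm`, `dU_total_kBT`,
#'   `t90_us`, `fit_K_m_s`, `fit_decay_nm`, `ok`.
#' @export
summary_table <- function(results) {
  stopifnot(inherits(results, "ez_result_set"))
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    if (inherits(r, "ez_failed"))
      return(data.frame(id = id, geometry = NA, c_mM = NA, start_rule = NA,
                        lambda_D_nm = NA, ez_horizon_nm = NA, ez_10us_nm = NA,
                        dU_total_kBT = NA, t90_us = NA, fit_K_m_s = NA,
                        fit_decay_nm = NA, ok = FALSE))
    scn <- r$scenario
    data.frame(
      id = id, geometry = scn$surface$kind, c_mM = scn$medium$c_s,
      start_rule = scn$start_rule,
      lambda_D_nm = debye_length(scn$medium) * 1e9,
      ez_horizon_nm = r$summary$ez_at_horizon_m * 1e9,
      ez_10us_nm = r$summary$ez_at_10us_m * 1e9,
      dU_total_kBT = r$summary$dU_total_kBT,
      t90_us = r$summary$time_to_90pct_s * 1e6,
      fit_K_m_s = r$fit$K, fit_decay_nm = 1e9 / r$fit$kappa,
      ok = TRUE)
  })
  do.call(rbind, rows)
}

#' Write per-scenario CSVs and the combined summary
#'
#' @param results An [run_scenarios()] result set.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the summary data.frame.
#' @export
write_results <- function(results, output_dir) {
  stopifnot(inherits(results, "ez_result_set"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(results)) {
    r <- results[[id]]
    if (inherits(r, "ez_failed")) next
    utils::write.csv(trajectory_table(r),
                     file.path(output_dir, paste0(id, "_trajectory.csv")),
                     row.names = FALSE)
    utils::write.csv(r$energy,
                     file.path(output_dir, paste0(id, "_energy.csv")),
                     row.names = FALSE)
  }
  smry <- summary_table(results)
  utils::write.csv(smry, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(smry)
}

#' Trajectory table in reporting units
#'
#' @param result An [run_scenario()] result.
#' @return A data.frame with columns `t_us`, `x_nm`, `relative_distance_nm`,
#'   `v_m_per_s`, `F_N`, `U_kBT`.
#' @export
trajectory_table <- function(result) {
  stopifnot(inherits(result, "ez_result"))
  tr <- result$trajectory
  scn <- result$scenario
  sol <- attr(tr, "solution")
  data.frame(
    t_us = tr$t * 1e6,
    x_nm = tr$x * 1e9,
    relative_distance_nm = (tr$x - tr$x[1]) * 1e9,
    v_m_per_s = tr$v,
    F_N = force(sol, tr$x, scn$probe$Q_eff),
    U_kBT = energy_in_kBT(probe_energy(sol, tr$x, scn$probe$Q_eff),
                          scn$medium$T))
}
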