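# Human-editable YAML scenario configuration.
#
# Config units follow lab conventions (nm, mM, us, charges in e); everything
# is converted to SI on load. A config with no `scenarios` key expands to
# the twelve default tubulin scenarios.

#' Read a scenario configuration file
#'
#' Parses a YAML file declaring scenarios and optional solver controls. Each
#' scenario entry supports:
#' \describe{
#'   \item{`geometry`}{`cylinder`, `sphere` or `plane` (required).}
#'   \item{`concentration_mM`}{salt concentration in mM (required).}
#'   \item{`start_rule`}{`stern_contact` (default) or `probe_contact`.}
#'   \item{`horizon_us`}{time horizon in microseconds (default 50).}
#'   \item{`radius_nm`, `stern_nm`, `sigma_C_m2`}{surface overrides;
#'     defaults are the canonical tubulin values for the geometry.}
#'   \item{`probe_radius_nm`, `probe_charge_e`, `probe_charge_eff_e`,
#'     `probe_mass_kDa`}{probe overrides; `probe_charge_eff_e` is required
#'     at concentrations other than 10 or 160 mM, where no tabulated
#'     effective charge exists.}
#'   \item{`epsilon_r`, `temperature_K`, `viscosity_Pa_s`}{medium overrides.}
#' }
#' A top-level `solver` block (`mode`, `rtol`, `atol`) is returned as an
#' attribute.
#'
#' @param path Path to the YAML file.
#' @return Named list of [scenario()] objects with attribute `solver`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$scenarios
  if (is.null(entries))
    return(structure(tubulin_scenarios(), solver = cfg$solver))
  e_chg <- .const$e
  out <- list()
  for (i in seq_along(entries)) {
    en <- entries[[i]]
    if (is.null(en$geometry) || is.null(en$concentration_mM))
      .stop_invalid("scenario %d: `geometry` and `concentration_mM` are required", i)
    kind <- match.arg(en$geometry, c("cylinder", "sphere", "plane"))
    c_mM <- en$concentration_mM
    defaults <- .default_conditions()[[kind]]
    md <- medium(
      epsilon_r = en$epsilon_r %||% 78.3,
      temperature = en$temperature_K %||% 293.15,
      viscosity = en$viscosity_Pa_s %||% 1e-3,
      concentration_mM = c_mM)
    surf <- charged_surface(
      kind,
      radius = if (kind == "plane") NULL
               else (en$radius_nm %||% (defaults$radius * 1e9)) * 1e-9,
      stern = (en$stern_nm %||% 0.33) * 1e-9,
      sigma = en$sigma_C_m2 %||% defaults$sigma)
    q_eff <- if (!is.null(en$probe_charge_eff_e)) en$probe_charge_eff_e * e_chg
             else tubulin_effective_charge(c_mM)
    pr <- probe(
      radius = (en$probe_radius_nm %||% 2.71) * 1e-9,
      charge_bare = (en$probe_charge_e %||% -52) * e_chg,
      charge_eff = q_eff,
      mass = (en$probe_mass_kDa %||% 110) * 1000 * .const$dalton)
    id <- en$id %||% sprintf("%s_%gmM_%s", kind, c_mM,
                             en$start_rule %||% "stern_contact")
    out[[id]] <- scenario(surf, md, pr,
                          start_rule = en$start_rule %||% "stern_contact",
                          t_max = (en$horizon_us %||% 50) * 1e-6)
  }
  structure(out, solver = cfg$solver)
}

#' Write scenarios to a configuration file
#'
#' Serialises a list of scenarios to the YAML layout accepted by
#' [read_scenario_config()] (lengths in nm, charges in e, horizons in us).
#'
#' @param scenarios Named list of [scenario()] objects.
#' @param path Output file path.
#' @param solver Optional solver-control list stored verbatim.
#' @param header Optional comment line (e.g. the generating seed) written at
#'   the top of the file.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(scenarios, path, solver = NULL,
                                  header = NULL) {
  e_chg <- .const$e
  entries <- lapply(names(scenarios), function(id) {
    s <- scenarios[[id]]
    en <- list(
      id = id,
      geometry = s$surface$kind,
      concentration_mM = s$medium$c_s,
      start_rule = s$start_rule,
      horizon_us = s$t_max * 1e6,
      stern_nm = s$surface$d * 1e9,
      sigma_C_m2 = s$surface$sigma,
      probe_radius_nm = s$probe$a * 1e9,
      probe_charge_e = s$probe$Q_bare / e_chg,
      probe_charge_eff_e = s$probe$Q_eff / e_chg,
      probe_mass_kDa = s$probe$m / .const$dalton / 1000,
      epsilon_r = s$medium$epsilon_r,
      temperature_K = s$medium$T,
      viscosity_Pa_s = s$medium$eta)
    if (s$surface$kind != "plane") en$radius_nm <- s$surface$R * 1e9
    en
  })
  cfg <- list(scenarios = entries)
  if (!is.null(solver)) cfg$solver <- solver
  txt <- yaml::as.yaml(cfg)
  if (!is.null(header)) txt <- paste0("# ", header, "\n", txt)
  writeLines(txt, path)
  invisible(path)
}
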