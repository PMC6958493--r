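#' Kinetic and plate-scenario settings
#'
#' Controls the nonequilibrium distortion applied to equilibrium bound
#' fractions. Association is modelled as pseudo-first order: with antigen in
#' large excess over antibody the free antigen stays at its initial value,
#' so the rate constant is kon' = kon * ag0 and the approach to equilibrium
#' is mono-exponential. Dissociation during the association phase is
#' neglected (irreversible approximation), so the model is meaningful for
#' slow-binding, high-affinity complexes.
#'
#' Three plate scenarios are supported: `"unsaturated"` (all applied antigen
#' coats), `"saturated"` (applied levels above `saturation_cap` all coat the
#' cap), and `"saturated_desorbing"` (saturated, plus a constant fractional
#' loss of complex at the capped wells modelling desorption from the
#' polystyrene surface).
#'
#' @param kon Association rate constant (nM^-1 min^-1), >= 0.
#' @param time Incubation time (minutes), >= 0; `Inf` means equilibrium.
#' @param scenario One of `"unsaturated"`, `"saturated"`,
#'   `"saturated_desorbing"`.
#' @param saturation_cap Maximum coatable antigen concentration (nM);
#'   default 30, a conservative figure for a high-binding 96-well plate and
#'   a large antigen.
#' @param desorption_factor Multiplier in (0, 1\] applied to bound fractions
#'   at capped antigen levels in the desorbing scenario; default 0.9 (10%
#'   loss, time-independent).
#' @return An object of class `kinetic_settings`.
#' @export
kinetic_settings <- function(kon = 0.0001444, time = 1200,
                             scenario = c("unsaturated", "saturated",
                                          "saturated_desorbing"),
                             saturation_cap = 30, desorption_factor = 0.9) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(kon), length(kon) == 1L, kon >= 0,
            is.numeric(time), length(time) == 1L, time >= 0,
            is.numeric(saturation_cap), saturation_cap > 0,
            is.numeric(desorption_factor))
  if (desorption_factor <= 0 || desorption_factor > 1)
    stop("`desorption_factor` must lie in (0, 1]")
  structure(list(kon = kon, time = time, scenario = scenario,
                 saturation_cap = saturation_cap,
                 desorption_factor = desorption_factor),
            class = "kinetic_settings")
}

#' Integrated pseudo-first-order rate factor
#'
#' The fraction of the eventual equilibrium binding reached after time `t`:
#' 1 - exp(-kon * ag0 * t). Equals 0 at t = 0 and tends to 1 as t grows;
#' increasing in each argument. Lower antigen levels equilibrate more
#' slowly because the antigen concentration sits inside the rate constant.
#'
#' @param kon Association rate constant (nM^-1 min^-1), >= 0.
#' @param ag0 Total antigen concentration(s) (nM), >= 0.
#' @param t Time (minutes), >= 0.
#' @return Factor(s) in \[0, 1\].
#' @export
integrated_rate_factor <- function(kon, ag0, t) {
  if (any(kon < 0) || any(ag0 < 0) || any(t < 0))
    stop("`kon`, `ag0` and `t` must be >= 0")
  -expm1(-kon * ag0 * t)
}

#' Half-time of complex formation
#'
#' Under pseudo-first-order association the half-time of complex formation
#' depends only on the antigen level: t_half = ln(2) / (kon * ag0).
#'
#' @param kon Association rate constant (nM^-1 min^-1).
#' @param ag0 Total antigen concentration (nM).
#' @return Half-time(s) in minutes.
#' @export
half_time <- function(kon, ag0) {
  if (any(kon * ag0 <= 0)) stop("`kon * ag0` must be > 0")
  log(2) / (kon * ag0)
}

#' Association rate constant from an observed half-time
#'
#' Inverts [half_time()]: kon = ln(2) / (t_half * ag0). This is how a
#' representative kon is read off a kinetic assay: the time to half of the
#' maximum bound fraction at a reference antigen level.
#'
#' @param t_half Observed half-time (minutes), > 0.
#' @param ag0 Antigen concentration at which it was observed (nM), > 0.
#' @return Rate constant (nM^-1 min^-1).
#' @examples
#' kon_from_half_time(240, 20)  # ~1.444e-4
#' @export
kon_from_half_time <- function(t_half, ag0) {
  if (any(t_half <= 0) || any(ag0 <= 0))
    stop("`t_half` and `ag0` must be > 0")
  log(2) / (t_half * ag0)
}

#' Distort a bound-fraction grid for unattained equilibrium
#'
#' Multiplies every cell by its own integrated rate factor, which depends on
#' the cell's coated antigen concentration. Output is cellwise at or below
#' the input; the distortion is strongest at low antigen.
#'
#' @param grid A `bf_grid` of equilibrium bound fractions.
#' @param settings A [kinetic_settings()] object.
#' @return A `bf_grid` of nonequilibrium bound fractions.
#' @export
apply_kinetics <- function(grid, settings) {
  stopifnot(inherits(grid, "bf_grid"), inherits(settings, "kinetic_settings"))
  if (!is.finite(settings$time)) return(grid)
  f <- integrated_rate_factor(settings$kon, grid$antigen$coated,
                              settings$time)
  values <- sweep(grid$values, 2, f, `*`)
  bf_grid(grid$kd, grid$antigen, values, validate = FALSE)
}

#' Antigen series for a plate scenario
#'
#' The standard seven-level assay layout applies
#' \{1.25, 2.5, 5, 10, 20, 40, 80\} nM. On an unsaturated plate all of it
#' coats. On a saturated plate the levels above the cap coat only the cap,
#' so the coated vector ends in a duplicated tail (with the default 30 nM
#' cap: \{1.25, 2.5, 5, 10, 20, 30, 30\}) while the nominal labels remain
#' 40 and 80.
#'
#' @param scenario One of `"unsaturated"`, `"saturated"`,
#'   `"saturated_desorbing"`.
#' @param saturation_cap Maximum coatable antigen (nM); default 30.
#' @param nominal Applied concentrations (nM); default the standard series.
#' @return An [antigen_series()].
#' @export
build_antigen_series <- function(scenario = c("unsaturated", "saturated",
                                              "saturated_desorbing"),
                                 saturation_cap = 30,
                                 nominal = c(1.25, 2.5, 5, 10, 20, 40, 80)) {
  scenario <- match.arg(scenario)
  if (scenario == "unsaturated")
    antigen_series(nominal)
  else
    antigen_series(nominal, coated = pmin(nominal, saturation_cap))
}

#' Apply surface desorption to a saturated grid
#'
#' Models the time-independent loss of antigen-antibody complex from the
#' saturated polystyrene surface: cells whose coated antigen equals the
#' saturation cap are multiplied by `desorption_factor`; all other cells are
#' untouched.
#'
#' @param grid A `bf_grid` built on a saturated antigen series.
#' @param settings A [kinetic_settings()] with
#'   `scenario = "saturated_desorbing"`.
#' @return A `bf_grid`.
#' @export
apply_desorption <- function(grid, settings) {
  stopifnot(inherits(grid, "bf_grid"), inherits(settings, "kinetic_settings"))
  if (settings$scenario != "saturated_desorbing")
    stop("desorption applies only to scenario \"saturated_desorbing\"")
  at_cap <- grid$antigen$coated == settings$saturation_cap
  if (!any(at_cap))
    stop("no antigen level sits at the saturation cap; ",
         "is the grid built on a saturated series?")
  values <- grid$values
  values[, at_cap] <- values[, at_cap] * settings$desorption_factor
  bf_grid(grid$kd, grid$antigen, values, validate = FALSE)
}

#' Scenario grid: equilibrium isotherm plus kinetic and plate artefacts
#'
#' Convenience pipeline: builds the scenario's antigen series, generates the
#' equilibrium grid with the exact depletion model, applies the kinetic
#' distortion (if `time` is finite) and, in the desorbing scenario, the
#' desorption multiplier.
#'
#' @param params A [binding_parameters()] object.
#' @param kd_axis KD axis (nM); defaults to the single `params$kd`.
#' @param settings A [kinetic_settings()] object.
#' @param antigen Optional [antigen_series()] overriding the scenario
#'   default.
#' @return A `bf_grid`.
#' @export
scenario_grid <- function(params, kd_axis = params$kd,
                          settings = kinetic_settings(),
                          antigen = NULL) {
  if (is.null(antigen))
    antigen <- build_antigen_series(settings$scenario,
                                    settings$saturation_cap)
  g <- ideal_grid(kd_axis, antigen, params)
  g <- apply_kinetics(g, settings)
  if (settings$scenario == "saturated_desorbing")
    g <- apply_desorption(g, settings)
  g
}

#' Time course of complex formation
#'
#' Bound-fraction trajectories over time for each antigen level at a single
#' KD: the equilibrium value times the integrated rate factor at each time
#' (with desorption applied at capped levels in the desorbing scenario).
#' Saturated levels share one rate constant, so their trajectories grow in
#' parallel -- the kinetic signature of a saturated plate.
#'
#' @param params A [binding_parameters()] object (its `kd` is the curve's
#'   KD).
#' @param settings A [kinetic_settings()] object.
#' @param times Time points (minutes), positive.
#' @param antigen Optional [antigen_series()] overriding the scenario
#'   default.
#' @return A data frame of class `irfa_time_course` with columns
#'   `time_min`, `ag0_nM` (nominal), `ag0_coated_nM`, `bound_fraction`.
#' @export
time_course <- function(params, settings = kinetic_settings(),
                        times = c(15, 30, 60, 120, 240, 480, 960, 1440, 2880),
                        antigen = NULL) {
  stopifnot(length(times) >= 1L, all(is.finite(times)), all(times > 0))
  if (is.null(antigen))
    antigen <- build_antigen_series(settings$scenario,
                                    settings$saturation_cap)
  eq <- bound_fraction_exact(antigen$coated, params)
  if (settings$scenario == "saturated_desorbing") {
    at_cap <- antigen$coated == settings$saturation_cap
    eq[at_cap] <- eq[at_cap] * settings$desorption_factor
  }
  out <- do.call(rbind, lapply(times, function(t) {
    f <- integrated_rate_factor(settings$kon, antigen$coated, t)
    data.frame(time_min = t, ag0_nM = antigen$nominal,
               ag0_coated_nM = antigen$coated, bound_fraction = eq * f)
  }))
  class(out) <- c("irfa_time_course", "data.frame")
  out
}

#' Write a time course to CSV
#'
#' @param tc An `irfa_time_course` data frame.
#' @param path Output file path.
#' @param meta Named character vector of comment-header metadata.
#' @return `path`, invisibly.
#' @export
write_time_course_csv <- function(tc, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# irfa time course", con)
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.csv(as.data.frame(tc)[, c("time_min", "ag0_nM",
                                         "bound_fraction")],
                   con, row.names = FALSE)
  invisible(path)
}
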