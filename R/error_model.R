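#' Stochastic noise model for the assay
#'
#' The four error sources propagated to the bound fraction: the amount of
#' coated antigen (serial-dilution and coating-uniformity error, relative),
#' the pipetted amount of antibody (relative), well-to-well variation of
#' nonspecific binding (expressed as the blank wells' relative SD), and the
#' gamma-counter noise (a constant SD in bound-fraction units). Defaults
#' are representative laboratory figures: 10% on antigen, 1% on antibody,
#' 1.5% blank SD, 0.01 counter SD.
#'
#' @param rel_err_antigen Relative error on the coated antigen amount.
#' @param rel_err_antibody Relative error on the applied antibody amount.
#' @param blank_sd_fraction Relative SD of the blank-well counts.
#' @param counter_sd Gamma-counter SD in bound-fraction units.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rel_err_antigen = 0.10, rel_err_antibody = 0.01,
                        blank_sd_fraction = 0.015, counter_sd = 0.01) {
  vals <- c(rel_err_antigen, rel_err_antibody, blank_sd_fraction, counter_sd)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals < 0)) stop("noise components must be >= 0")
  structure(list(rel_err_antigen = rel_err_antigen,
                 rel_err_antibody = rel_err_antibody,
                 blank_sd_fraction = blank_sd_fraction,
                 counter_sd = counter_sd),
            class = "noise_model")
}

#' Apparent bound fraction under an antibody-volume error
#'
#' A volumetric error in the applied antibody does not change the true
#' bound fraction (antigen in excess), but the blank-based estimate of T
#' does not track it, producing the apparent value
#' B'/T = B/T - (dT/T) * (1 - B/T). At complete binding the error
#' vanishes: with no unbound antibody there is nothing to mis-scale.
#'
#' @param bound_fraction True bound fraction(s) in \[0, 1\].
#' @param delta_t_over_t Signed relative error on T.
#' @return Apparent bound fraction(s).
#' @export
antibody_error_transform <- function(bound_fraction, delta_t_over_t) {
  if (any(bound_fraction < -1e-12) || any(bound_fraction > 1 + 1e-12))
    stop("`bound_fraction` must lie in [0, 1]")
  bound_fraction - delta_t_over_t * (1 - bound_fraction)
}

# Bound fraction for perturbed coated antigen, through the full scenario
# pipeline: exact isotherm, rate factor (optionally using the perturbed
# antigen), desorption at capped cells (positional, from the unperturbed
# series). `scale` perturbs the coated amounts.
perturbed_scenario_values <- function(params, kd_axis, antigen, settings,
                                      scale, perturb_rate_factor = TRUE) {
  coated <- antigen$coated * scale
  vals <- t(vapply(kd_axis, function(kd)
    bound_fraction_exact(coated, params, kd = kd),
    numeric(length(coated))))
  if (!is.null(settings) && is.finite(settings$time)) {
    ag_rate <- if (perturb_rate_factor) coated else antigen$coated
    f <- integrated_rate_factor(settings$kon, ag_rate, settings$time)
    vals <- sweep(vals, 2, f, `*`)
  }
  if (!is.null(settings) && settings$scenario == "saturated_desorbing") {
    at_cap <- antigen$coated == settings$saturation_cap
    vals[, at_cap] <- vals[, at_cap] * settings$desorption_factor
  }
  vals
}

#' Per-cell SD of the bound fraction due to antigen-amount error
#'
#' For each grid cell, the sample SD of the triplet of bound fractions
#' computed at \{1 - e, 1, 1 + e\} times the coated antigen (default
#' e = 10%), each propagated through the full model. When kinetic settings
#' are supplied the perturbed antigen also enters the rate factor (the
#' coated amount governs both the equilibrium level and the association
#' rate); `perturb_rate_factor = FALSE` restricts the perturbation to the
#' isotherm. The SD peaks where KD is comparable to ag0 and vanishes in
#' both extremes.
#'
#' @param params A [binding_parameters()] object.
#' @param kd_axis KD axis (nM).
#' @param antigen An [antigen_series()] or numeric vector (nM).
#' @param settings Optional [kinetic_settings()]; `NULL` for equilibrium.
#' @param noise A [noise_model()]; only `rel_err_antigen` is used.
#' @param perturb_rate_factor Whether the perturbed antigen enters the
#'   integrated rate factor as well as the isotherm (default `TRUE`).
#' @return A matrix of SDs (bound-fraction units) on the grid axes.
#' @export
sd_antigen_grid <- function(params, kd_axis, antigen, settings = NULL,
                            noise = noise_model(),
                            perturb_rate_factor = TRUE) {
  antigen <- as_antigen_series(antigen)
  e <- noise$rel_err_antigen
  lo <- perturbed_scenario_values(params, kd_axis, antigen, settings, 1 - e,
                                  perturb_rate_factor)
  mid <- perturbed_scenario_values(params, kd_axis, antigen, settings, 1,
                                   perturb_rate_factor)
  hi <- perturbed_scenario_values(params, kd_axis, antigen, settings, 1 + e,
                                  perturb_rate_factor)
  triplet_sd(lo, mid, hi)
}

# Sample SD (n - 1 = 2 denominator) of three equally shaped matrices.
# With the sample convention, the symmetric triplet {x - d, x, x + d} has
# SD exactly d, which is what pins the antibody-error SD to
# rel_err * (1 - B/T).
triplet_sd <- function(a, b, c) {
  m <- (a + b + c) / 3
  sqrt(((a - m)^2 + (b - m)^2 + (c - m)^2) / 2)
}

#' Per-cell SD of the bound fraction due to antibody-amount error
#'
#' Sample SD of the triplet \{B/T, B'/T at +e, B'/T at -e\} where B'/T is
#' the apparent bound fraction of [antibody_error_transform()] and
#' e = `rel_err_antibody`. Because the transform is linear and symmetric,
#' this equals e * (1 - B/T) exactly: proportional to the unbound fraction.
#'
#' @param grid A `bf_grid` (kinetics-distorted or not).
#' @param rel_err_antibody Relative error on T (default 1%).
#' @return A matrix of SDs on the grid axes.
#' @export
sd_antibody_grid <- function(grid, rel_err_antibody = 0.01) {
  stopifnot(inherits(grid, "bf_grid"))
  bf <- grid$values
  up <- antibody_error_transform(bf, rel_err_antibody)
  dn <- antibody_error_transform(bf, -rel_err_antibody)
  triplet_sd(dn, bf, up)
}

#' Constant SD of the bound fraction due to nonspecific-binding variation
#'
#' Blank subtraction propagates the blank-well uncertainty twice (once in
#' the blank itself, once in the well's implied total), so the SD of the
#' specifically bound fraction is the quadratic combination of two equal
#' terms: sqrt(2) * blank_sd_fraction. Constant over the grid.
#'
#' @param noise A [noise_model()]; only `blank_sd_fraction` is used.
#' @return A single SD in bound-fraction units (~0.0212 at the default).
#' @export
sd_nonspecific <- function(noise = noise_model()) {
  sqrt(2) * noise$blank_sd_fraction
}

#' Quadratic sum of the four error components
#'
#' Cellwise sqrt of the sum of squared SDs. Scalars (the nonspecific and
#' counter components) are recycled over the grid.
#'
#' @param sd_ag Antigen-error SD matrix.
#' @param sd_ab Antibody-error SD matrix (same dimensions).
#' @param sd_ns Nonspecific-binding SD (scalar or matrix).
#' @param sd_counter Counter SD (scalar or matrix).
#' @return A matrix of overall SDs; each cell is at least as large as every
#'   component.
#' @export
overall_sd_grid <- function(sd_ag, sd_ab, sd_ns, sd_counter) {
  sd_ag <- as.matrix(sd_ag)
  sd_ab <- as.matrix(sd_ab)
  if (!identical(dim(sd_ag), dim(sd_ab)))
    stop("`sd_ag` and `sd_ab` must have identical dimensions")
  for (x in list(sd_ns, sd_counter))
    if (is.matrix(x) && !identical(dim(x), dim(sd_ag)))
      stop("matrix components must share the grid dimensions")
  sqrt(sd_ag^2 + sd_ab^2 + sd_ns^2 + sd_counter^2)
}

#' Overall SD grid for a scenario in one call
#'
#' Builds the kinetics-adjusted antigen and antibody SD matrices on the
#' scenario's distorted bound fractions and combines them with the constant
#' nonspecific and counter SDs.
#'
#' @inheritParams sd_antigen_grid
#' @return A list with matrices `sd_antigen`, `sd_antibody`, scalars
#'   `sd_nonspecific`, `sd_counter`, matrix `overall`, and the distorted
#'   `grid` (a `bf_grid`).
#' @export
error_budget <- function(params, kd_axis, settings = NULL,
                         antigen = NULL, noise = noise_model(),
                         perturb_rate_factor = TRUE) {
  if (is.null(antigen)) {
    antigen <- if (is.null(settings)) build_antigen_series("unsaturated")
               else build_antigen_series(settings$scenario,
                                         settings$saturation_cap)
  }
  antigen <- as_antigen_series(antigen)
  grid <- if (is.null(settings))
    ideal_grid(kd_axis, antigen, params)
  else
    scenario_grid(params, kd_axis, settings, antigen)
  sd_ag <- sd_antigen_grid(params, kd_axis, antigen, settings, noise,
                           perturb_rate_factor)
  sd_ab <- sd_antibody_grid(grid, noise$rel_err_antibody)
  sd_ns <- sd_nonspecific(noise)
  list(sd_antigen = sd_ag, sd_antibody = sd_ab, sd_nonspecific = sd_ns,
       sd_counter = noise$counter_sd,
       overall = overall_sd_grid(sd_ag, sd_ab, sd_ns, noise$counter_sd),
       grid = grid)
}

#' Coefficient-of-variation grid
#'
#' Cellwise SD divided by the mean bound fraction. Cells with non-positive
#' mean have no defined CV; they are returned as `NA` and counted in the
#' `n_undefined` attribute rather than raising an error.
#'
#' @param sd SD matrix.
#' @param mean_grid A `bf_grid` (or matrix) of mean bound fractions on the
#'   same axes.
#' @return A matrix of CVs (dimensionless) with attribute `n_undefined`.
#' @export
cv_grid <- function(sd, mean_grid) {
  m <- if (inherits(mean_grid, "bf_grid")) mean_grid$values
       else as.matrix(mean_grid)
  sd <- as.matrix(sd)
  if (!identical(dim(sd), dim(m)))
    stop("`sd` and `mean_grid` must share dimensions")
  out <- sd / m
  undef <- m <= 0
  out[undef] <- NA_real_
  attr(out, "n_undefined") <- sum(undef)
  out
}
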