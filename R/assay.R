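#' Read per-well gamma-counter records
#'
#' CSV dialect: header `well,ag0_nM,counts,is_blank,role` with
#' `role` in \{`well`, `blank`, `t_tube`\}; `#`-prefixed comment lines are
#' skipped. Blank wells (blocked, uncoated) carry no antigen
#' concentration; total-activity tubes record the applied antibody as an
#' internal control. Kinetic tables add a `time_min` column.
#'
#' @param path CSV file path.
#' @return An object of class `plate_counts` (a validated data frame).
#' @export
read_plate_counts <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  plate_counts(df)
}

#' Validate a per-well count table
#'
#' @param df Data frame with columns `well`, `ag0_nM`, `counts`,
#'   `is_blank`, `role` (and optionally `time_min`).
#' @return A `plate_counts` object.
#' @export
plate_counts <- function(df) {
  need <- c("well", "ag0_nM", "counts", "is_blank", "role")
  if (!all(need %in% names(df)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  df$is_blank <- as.logical(df$is_blank)
  if (any(!df$role %in% c("well", "blank", "t_tube")))
    stop("`role` must be one of well, blank, t_tube")
  if (any(df$counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  if (!any(df$role == "blank")) stop("at least one blank well is required")
  if (any(df$role == "blank" & !is.na(df$ag0_nM) & df$ag0_nM > 0))
    stop("blank wells must not carry an antigen concentration")
  structure(df, class = c("plate_counts", "data.frame"))
}

#' Specifically bound counts from a well's supernatant
#'
#' Blank subtraction: the specifically bound activity is the mean blank
#' supernatant minus the well's supernatant, B_spec = U_blank_mean - U.
#' Negative values (possible under noise) are returned as-is; downstream
#' code flags rather than clips them, so the estimators see the same data
#' a naive analysis would.
#'
#' @param u Supernatant counts of the coated well(s).
#' @param u_blank_mean Mean supernatant counts of the blank wells.
#' @return Specifically bound counts (may be negative).
#' @export
specific_bound <- function(u, u_blank_mean) {
  if (any(u < 0) || any(u_blank_mean < 0)) stop("counts must be >= 0")
  u_blank_mean - u
}

#' Reduce a plate of counts to saturation-curve points
#'
#' Implements the blank-based plate arithmetic: the working total is
#' T = mean blank supernatant (the blanks lose only nonspecific binding,
#' which is invariant across wells), so each well's bound fraction is
#' (U_blank_mean - U) / U_blank_mean. The separate total-activity tubes
#' serve only as the internal control for nonspecific binding,
#' B_NS = mean(T tubes) - mean(U_blank). Replicate wells at the same
#' antigen level are averaged and their SD attached.
#'
#' @param plate A `plate_counts` object.
#' @return A list with `points` (data frame `ag0`, `bound_fraction`, `sd`,
#'   `n`), `t_estimate` (mean blank counts), `b_ns` (nonspecific counts,
#'   `NA` without t_tubes), `blank_cv` (SD/mean of blank wells) and
#'   `n_negative` (count of negative bound fractions, warned about).
#' @export
reduce_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_counts"))
  blanks <- plate$counts[plate$role == "blank"]
  wells <- plate[plate$role == "well", , drop = FALSE]
  if (length(unique(wells$ag0_nM)) < 2L)
    stop("at least 2 antigen levels are required")
  u_blank <- mean(blanks)
  per_well_bf <- specific_bound(wells$counts, u_blank) / u_blank
  levels_ag <- sort(unique(wells$ag0_nM))
  points <- do.call(rbind, lapply(levels_ag, function(a) {
    v <- per_well_bf[wells$ag0_nM == a]
    data.frame(ag0 = a, bound_fraction = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  n_neg <- sum(points$bound_fraction < 0)
  if (n_neg > 0)
    warning(sprintf("%d antigen level(s) with negative bound fraction (noise); reported unclipped", n_neg))
  t_tubes <- plate$counts[plate$role == "t_tube"]
  b_ns <- if (length(t_tubes)) mean(t_tubes) - u_blank else NA_real_
  list(points = points, t_estimate = u_blank, b_ns = b_ns,
       blank_cv = if (length(blanks) > 1) stats::sd(blanks) / u_blank
                  else NA_real_,
       n_negative = n_neg)
}

#' Generate a synthetic plate of gamma counts
#'
#' Simulator-backed generator of realistic per-well count tables for
#' end-to-end testing and demonstrations: equilibrium (or
#' kinetics-distorted) bound fractions plus the package noise model,
#' expressed as supernatant counts around a nominal blank level. All
#' output is synthetic.
#'
#' @param params A [binding_parameters()] object.
#' @param settings Optional [kinetic_settings()]; `NULL` for equilibrium.
#' @param antigen An [antigen_series()] or numeric vector (nM).
#' @param noise A [noise_model()].
#' @param n_replicate_wells Wells per antigen level (default 3).
#' @param blank_counts Nominal blank supernatant level (cpm).
#' @param b_ns_counts Nonspecific binding (cpm) separating the total tubes
#'   from the blanks.
#' @param seed Integer seed.
#' @return A `plate_counts` object.
#' @export
simulate_plate_counts <- function(params, settings = NULL,
                                  antigen = build_antigen_series("unsaturated"),
                                  noise = noise_model(),
                                  n_replicate_wells = 3,
                                  blank_counts = 10000,
                                  b_ns_counts = 500, seed = 1L) {
  antigen <- as_antigen_series(antigen)
  grid <- if (is.null(settings))
    ideal_grid(params$kd, antigen, params)
  else
    scenario_grid(params, params$kd, settings, antigen)
  eb_sd <- overall_sd_grid(
    sd_antigen_grid(params, params$kd, antigen, settings, noise),
    sd_antibody_grid(grid, noise$rel_err_antibody),
    sd_nonspecific(noise), noise$counter_sd)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(substream_seed(seed, 1L, 1L), kind = "Mersenne-Twister")
  rows <- list()
  wid <- 0L
  for (k in seq_along(antigen$nominal)) {
    bf <- stats::rnorm(n_replicate_wells, grid$values[1, k], eb_sd[1, k])
    for (v in bf) {
      wid <- wid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        well = sprintf("W%02d", wid), ag0_nM = antigen$nominal[k],
        counts = max(0, blank_counts * (1 - v)), is_blank = FALSE,
        role = "well")
    }
  }
  blanks <- stats::rnorm(3, blank_counts,
                         noise$blank_sd_fraction * blank_counts)
  for (i in seq_along(blanks))
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("B%02d", i), ag0_nM = NA_real_,
      counts = max(0, blanks[i]), is_blank = TRUE, role = "blank")
  for (i in 1:3)
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("T%02d", i), ag0_nM = NA_real_,
      counts = blank_counts + b_ns_counts, is_blank = FALSE,
      role = "t_tube")
  plate_counts(do.call(rbind, rows))
}

#' Estimate the association rate constant from a kinetic series
#'
#' Reads the half-time of complex formation off a measured (or simulated)
#' time course at a reference antigen level: the first time at which the
#' trajectory crosses half of its maximum, located by linear interpolation
#' between the bracketing time points, then inverted through
#' [kon_from_half_time()].
#'
#' @param tc A data frame with columns `time_min`, `ag0_nM`,
#'   `bound_fraction` (e.g. a [time_course()] output or a kinetic-assay
#'   CSV).
#' @param ag0_ref Reference antigen level (nM) whose trajectory is used.
#' @return Estimated kon (nM^-1 min^-1), with attribute `t_half` (min).
#' @export
estimate_kon_from_kinetic_series <- function(tc, ag0_ref) {
  need <- c("time_min", "ag0_nM", "bound_fraction")
  if (!all(need %in% names(tc)))
    stop("`tc` must have columns: ", paste(need, collapse = ", "))
  d <- tc[abs(tc$ag0_nM - ag0_ref) <= 1e-9 * pmax(1, ag0_ref), ,
          drop = FALSE]
  if (nrow(d) < 2L) stop("no trajectory at `ag0_ref`")
  d <- d[order(d$time_min), ]
  y <- d$bound_fraction
  tmax <- max(y)
  if (tmax <= 0 || stats::sd(y) == 0)
    stop("flat or non-positive trajectory; cannot locate a half-maximum")
  half <- tmax / 2
  above <- which(y >= half)
  i <- above[1]
  if (i == 1L) {
    if (y[1] == half) return(structure(kon_from_half_time(d$time_min[1],
                                                          ag0_ref),
                                       t_half = d$time_min[1]))
    stop("trajectory starts above half-maximum; sample earlier time points")
  }
  # linear interpolation between the bracketing points
  t0 <- d$time_min[i - 1]; t1 <- d$time_min[i]
  y0 <- y[i - 1]; y1 <- y[i]
  t_half <- t0 + (half - y0) / (y1 - y0) * (t1 - t0)
  structure(kon_from_half_time(t_half, ag0_ref), t_half = t_half)
}

#' Well geometry of a coated microplate
#'
#' @param diameter Well diameter (mm); default 6.4 (standard 96-well
#'   plate).
#' @param volume Coating volume (uL); default 100.
#' @param binding_capacity Protein binding capacity of the high-binding
#'   polystyrene surface (ng/cm^2); default 500.
#' @return An object of class `well_geometry`.
#' @export
well_geometry <- function(diameter = 6.4, volume = 100,
                          binding_capacity = 500) {
  stopifnot(diameter > 0, volume >= 0, binding_capacity > 0)
  structure(list(diameter = diameter, volume = volume,
                 binding_capacity = binding_capacity),
            class = "well_geometry")
}

#' Wetted polystyrene surface area of a well
#'
#' Base disc plus the lateral band wetted by the coating volume: the well
#' is a cylinder, the liquid height is volume / base area, and the area in
#' contact with solution is base + perimeter * height. 1 uL = 1 mm^3.
#'
#' @param geom A [well_geometry()] object.
#' @return Area in mm^2 (94.7 for the defaults).
#' @export
well_surface_area <- function(geom = well_geometry()) {
  stopifnot(inherits(geom, "well_geometry"))
  radius <- geom$diameter / 2
  base <- pi * radius^2
  height <- geom$volume / base
  base + 2 * pi * radius * height
}

#' Maximum coatable antigen concentration
#'
#' The finite binding capacity of the polystyrene surface caps the antigen
#' that can actually coat a well. The bindable mass is capacity x wetted
#' area; since the capacity figure is only a one-significant-figure
#' estimate, the per-well mass is kept at that same precision by default
#' (500 ng for the default geometry) rather than quoting false precision,
#' matching the conventional figure of 50 nM for a 100 kDa antigen in a
#' 100 uL well. Set `mass_sig_digits = Inf` for the unrounded arithmetic.
#'
#' @param geom A [well_geometry()] object.
#' @param antigen_mw Antigen molecular weight (kDa), > 0.
#' @param mass_sig_digits Significant digits retained in the per-well
#'   bindable mass (default 1, the precision of the capacity figure).
#' @return Maximum coatable concentration (nM).
#' @examples
#' max_coated_antigen(well_geometry(), 100)  # 50 nM
#' max_coated_antigen(well_geometry(), 315)  # gp120 heptamer, ~15.9 nM
#' @export
max_coated_antigen <- function(geom = well_geometry(), antigen_mw,
                               mass_sig_digits = 1) {
  stopifnot(inherits(geom, "well_geometry"), antigen_mw > 0)
  area_cm2 <- well_surface_area(geom) / 100
  mass_ng <- geom$binding_capacity * area_cm2
  if (is.finite(mass_sig_digits))
    mass_ng <- signif(mass_ng, mass_sig_digits)
  # ng / uL / kDa -> umol/L scale: x1000 gives nmol/L
  1000 * mass_ng / geom$volume / antigen_mw
}
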