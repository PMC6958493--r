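#' Exact equilibrium bound fraction under antigen depletion
#'
#' Solves the mass-balance form of the Langmuir isotherm for the bound
#' fraction B/T when the bound antibody consumes a non-negligible share of
#' the antigen, so that the free antigen concentration is below the applied
#' total. Writing a = ag0 / T, the bound fraction x = B/T satisfies the
#' quadratic
#'
#'   x^2 - x * (kd/T + a + r) + r * a = 0,
#'
#' and the physically meaningful root is the smaller one: it passes through
#' the origin at ag0 = 0 and converges to `r` at infinite antigen.
#'
#' For large ag0/T the smaller root suffers catastrophic cancellation in the
#' textbook quadratic formula; the larger root is computed first and the
#' smaller obtained from the product of roots (r * a / larger), which is
#' stable for antigen-to-antibody ratios of many hundreds.
#'
#' @param ag0 Total applied antigen concentration(s) (nM), non-negative;
#'   vectorised.
#' @param params A [binding_parameters()] object.
#' @param kd Optional dissociation constant (nM) overriding `params$kd`
#'   (used when scanning a KD axis at otherwise fixed parameters).
#'
#' @return Bound fraction(s) B/T in \[0, min(r, ag0/T)\].
#' @examples
#' p <- binding_parameters(r = 0.7, kd = 1, t_total = 0.1)
#' bound_fraction_exact(c(1.25, 80), p)
#' @export
bound_fraction_exact <- function(ag0, params, kd = NULL) {
  stopifnot(inherits(params, "binding_parameters"))
  if (is.null(kd)) kd <- params$kd
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd))
  if (kd <= 0) stop("`kd` must be > 0")
  if (any(!is.finite(ag0)) || any(ag0 < 0))
    stop("`ag0` must be finite and >= 0")
  r <- params$r
  tt <- params$t_total
  a <- ag0 / tt
  s <- kd / tt + a + r
  disc <- s^2 - 4 * r * a
  if (any(disc < 1e-12 * pmax(1, s^2)))
    warning("near-coincident quadratic roots (discriminant ~ 0); ",
            "the bound fraction may be numerically delicate")
  disc <- pmax(disc, 0)
  larger <- (s + sqrt(disc)) / 2
  out <- ifelse(a == 0, 0, r * a / larger)
  pmin(pmax(out, 0), r)
}

#' Rectangular-hyperbola (Langmuir) bound fraction
#'
#' The depletion-free approximation of the binding isotherm,
#' B/T = r * ag0 / (ag0 + kd): strictly increasing in `ag0` with asymptote
#' `r`. This is the model the hyperbola estimator fits.
#'
#' @param ag0 Total antigen concentration(s) (nM), non-negative.
#' @param r Immunoreactive fraction (fraction).
#' @param kd Dissociation constant (nM), > 0.
#' @return Bound fraction(s).
#' @export
bound_fraction_hyperbola <- function(ag0, r, kd) {
  if (any(!is.finite(ag0)) || any(ag0 < 0))
    stop("`ag0` must be finite and >= 0")
  if (!is.numeric(kd) || any(kd <= 0)) stop("`kd` must be > 0")
  r * ag0 / (ag0 + kd)
}

#' Double-inverse (Lindmo) transform of saturation curve points
#'
#' Maps each point (ag0, B/T) to (1/ag0, T/B), the coordinates of the
#' Lindmo plot in which the ideal hyperbola becomes a straight line of
#' intercept 1/r and slope kd/r. Points with non-positive bound fraction
#' have no reciprocal: they are excluded and counted, never dropped
#' silently.
#'
#' @param points A data frame with columns `ag0` (nM) and `bound_fraction`.
#' @return A data frame with columns `inv_ag0` and `inv_bound_fraction`,
#'   input order preserved, with attribute `n_dropped` giving the number of
#'   excluded non-positive points.
#' @export
lindmo_transform <- function(points) {
  points <- validate_points(points, require_positive = FALSE)
  keep <- points$bound_fraction > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(sprintf("%d point(s) with non-positive bound fraction excluded from the Lindmo transform", n_dropped))
  out <- data.frame(inv_ag0 = 1 / points$ag0[keep],
                    inv_bound_fraction = 1 / points$bound_fraction[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

validate_points <- function(points, require_positive = TRUE) {
  if (!is.data.frame(points) ||
      !all(c("ag0", "bound_fraction") %in% names(points)))
    stop("`points` must be a data frame with columns `ag0` and `bound_fraction`")
  if (any(!is.finite(points$ag0)) || any(points$ag0 <= 0))
    stop("`ag0` must be finite and > 0")
  if (require_positive && all(points$bound_fraction <= 0))
    stop("all bound fractions are non-positive")
  points
}

#' Grid of bound fractions over a (KD, antigen) lattice
#'
#' The central exchange object of the package: a matrix of bound fractions
#' B/T with one row per dissociation constant and one column per antigen
#' level. Rows are generated with the exact depletion model
#' ([bound_fraction_exact()]); nonequilibrium and plate artefacts are
#' applied afterwards by [apply_kinetics()] and [apply_desorption()].
#'
#' @param kd_axis Dissociation constants (nM), positive.
#' @param antigen An [antigen_series()] or a numeric vector of antigen
#'   concentrations (nM).
#' @param params A [binding_parameters()] object (its `kd` is ignored; the
#'   axis supplies KD row by row).
#' @return An object of class `bf_grid`: list with `kd` (numeric axis),
#'   `antigen` (`antigen_series`) and `values` (matrix, rows = KD).
#' @examples
#' g <- ideal_grid(c(0.1, 1, 10), c(1.25, 2.5, 5, 10, 20, 40, 80),
#'                 binding_parameters(r = 0.7, kd = 1, t_total = 0.1))
#' g
#' @export
ideal_grid <- function(kd_axis, antigen, params) {
  stopifnot(is.numeric(kd_axis), length(kd_axis) >= 1L,
            all(is.finite(kd_axis)), all(kd_axis > 0))
  antigen <- as_antigen_series(antigen)
  values <- t(vapply(
    kd_axis,
    function(kd) bound_fraction_exact(antigen$coated, params, kd = kd),
    numeric(length(antigen))
  ))
  bf_grid(kd_axis, antigen, values)
}

#' Construct a bound-fraction grid
#'
#' @param kd Numeric KD axis (nM).
#' @param antigen An [antigen_series()] (or numeric vector).
#' @param values Matrix of bound fractions, `length(kd)` rows and
#'   `length(antigen)` columns.
#' @param validate If `TRUE` (default) enforce the ideal-grid invariants:
#'   values in \[0, 1\] and non-decreasing along each row. Noisy grids
#'   produced by the simulator set this to `FALSE`.
#' @return A `bf_grid` object.
#' @export
bf_grid <- function(kd, antigen, values, validate = TRUE) {
  antigen <- as_antigen_series(antigen)
  values <- as.matrix(values)
  if (nrow(values) != length(kd) || ncol(values) != length(antigen))
    stop("`values` must be length(kd) x length(antigen)")
  if (validate) {
    if (any(values < -1e-12) || any(values > 1 + 1e-12))
      stop("bound fractions must lie in [0, 1]")
    if (any(apply(values, 1, function(v) any(diff(v) < -1e-9))))
      stop("bound fractions must be non-decreasing in antigen within a KD row")
  }
  dimnames(values) <- list(format(kd, trim = TRUE),
                           format(antigen$nominal, trim = TRUE))
  structure(list(kd = as.numeric(kd), antigen = antigen, values = values),
            class = "bf_grid")
}

#' @export
print.bf_grid <- function(x, ...) {
  cat(sprintf("Bound-fraction grid: %d KD value(s) x %d antigen level(s)\n",
              length(x$kd), length(x$antigen)))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.data.frame.bf_grid <- function(x, ...) {
  data.frame(
    kd_nM = rep(x$kd, times = length(x$antigen)),
    ag0_nM = rep(x$antigen$nominal, each = length(x$kd)),
    ag0_coated_nM = rep(x$antigen$coated, each = length(x$kd)),
    bound_fraction = as.vector(x$values)
  )
}

#' Extract one KD row of a grid as saturation-curve points
#'
#' The points carry the nominal antigen labels, which is what an
#' experimenter would fit against (on a saturated plate the applied levels
#' are known; the coated amounts are not).
#'
#' @param grid A `bf_grid`.
#' @param kd The KD row to extract (matched within a small tolerance), or
#'   `NULL` if the grid has a single row.
#' @return A data frame with columns `ag0` and `bound_fraction`.
#' @export
grid_points <- function(grid, kd = NULL) {
  stopifnot(inherits(grid, "bf_grid"))
  if (is.null(kd)) {
    if (length(grid$kd) != 1L) stop("`kd` is required for a multi-row grid")
    i <- 1L
  } else {
    i <- which(abs(grid$kd - kd) <= 1e-9 * pmax(1, abs(kd)))
    if (length(i) != 1L) stop("`kd` does not match a unique grid row")
  }
  data.frame(ag0 = grid$antigen$nominal, bound_fraction = grid$values[i, ])
}

#' Write a grid (or SD/CV matrix on the same axes) to long-format CSV
#'
#' Columns `kd_nM`, `ag0_nM`, `value`, preceded by `#`-prefixed metadata
#' comment lines.
#'
#' @param grid A `bf_grid`, or a plain matrix accompanied by `kd` and
#'   `antigen`.
#' @param path Output file path.
#' @param meta Named character vector written as comment header lines.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, meta = character()) {
  df <- as.data.frame(grid)
  names(df)[names(df) == "bound_fraction"] <- "value"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# irfa grid export"), con)
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
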