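#' True system parameters for an immunoreactive fraction assay
#'
#' Bundles the parameters that drive every model in the package: the
#' immunoreactive fraction `r`, the equilibrium dissociation constant `kd`,
#' the association rate constant `kon` and the total applied antibody
#' concentration `t_total`. Internal units are fixed: concentrations in nM,
#' time in minutes, `r` stored as a fraction in \[0, 1\] and formatted as a
#' percentage only when printed. The dissociation rate constant
#' `koff = kon * kd` (min^-1) is derived.
#'
#' @param r Immunoreactive fraction, dimensionless in \[0, 1\].
#' @param kd Equilibrium dissociation constant (nM), strictly positive.
#' @param kon Association rate constant (nM^-1 min^-1), non-negative.
#'   The default is a representative value measured for a slow-binding
#'   radiolabeled antibody (half-time 240 min at 20 nM antigen).
#' @param t_total Total applied antibody concentration (nM), strictly
#'   positive.
#'
#' @return An object of class `binding_parameters`: a list with elements
#'   `r`, `kd`, `kon`, `t_total` and the derived `koff`.
#' @examples
#' binding_parameters(r = 0.7, kd = 1)
#' @export
binding_parameters <- function(r = 0.7, kd = 1, kon = 0.0001444,
                               t_total = 0.1) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(kd), length(kd) == 1L, is.finite(kd),
            is.numeric(kon), length(kon) == 1L, is.finite(kon),
            is.numeric(t_total), length(t_total) == 1L, is.finite(t_total))
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]")
  if (kd <= 0) stop("`kd` must be > 0")
  if (kon < 0) stop("`kon` must be >= 0")
  if (t_total <= 0) stop("`t_total` must be > 0")
  structure(
    list(r = r, kd = kd, kon = kon, t_total = t_total, koff = kon * kd),
    class = "binding_parameters"
  )
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat("Binding parameters\n")
  cat(sprintf("  r       : %.1f %%\n", 100 * x$r))
  cat(sprintf("  KD      : %g nM\n", x$kd))
  cat(sprintf("  kon     : %g nM^-1 min^-1\n", x$kon))
  cat(sprintf("  koff    : %g min^-1\n", x$koff))
  cat(sprintf("  [T]     : %g nM\n", x$t_total))
  invisible(x)
}

#' Ordered series of total antigen concentrations
#'
#' An antigen series carries two parallel vectors: `nominal`, the applied
#' solution concentrations an experimenter would label the wells with, and
#' `coated`, the concentrations actually presented on the plate surface.
#' They differ only when the polystyrene plate saturates: applied levels
#' above the plate's binding capacity all coat the same capped amount, so
#' the coated vector has a duplicated tail while the nominal labels remain
#' distinct. All computation uses `coated`; fitting and reporting use
#' `nominal`.
#'
#' @param nominal Applied total antigen concentrations (nM), positive and
#'   non-decreasing.
#' @param coated Coated concentrations (nM); defaults to `nominal`
#'   (unsaturated plate). Duplicated values are permitted only here.
#'
#' @return An object of class `antigen_series`.
#' @seealso [build_antigen_series()] for the standard assay layouts.
#' @export
antigen_series <- function(nominal, coated = nominal) {
  stopifnot(is.numeric(nominal), is.numeric(coated),
            length(nominal) == length(coated), length(nominal) >= 1L)
  if (any(!is.finite(nominal)) || any(!is.finite(coated)))
    stop("antigen concentrations must be finite")
  if (any(nominal <= 0) || any(coated <= 0))
    stop("antigen concentrations must be > 0")
  if (is.unsorted(nominal)) stop("`nominal` must be non-decreasing")
  if (anyDuplicated(nominal))
    stop("duplicated nominal levels are not allowed; duplicates arise only ",
         "in the coated vector of a saturated plate")
  structure(list(nominal = as.numeric(nominal), coated = as.numeric(coated)),
            class = "antigen_series")
}

#' @export
print.antigen_series <- function(x, ...) {
  cat("Antigen series (nM)\n")
  cat("  nominal:", paste(format(x$nominal), collapse = ", "), "\n")
  if (!identical(x$nominal, x$coated))
    cat("  coated :", paste(format(x$coated), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.antigen_series <- function(x) length(x$nominal)

as_antigen_series <- function(x) {
  if (inherits(x, "antigen_series")) return(x)
  antigen_series(as.numeric(x))
}
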