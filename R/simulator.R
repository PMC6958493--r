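#' Monte-Carlo simulation configuration
#'
#' The study conditions of the estimator comparison: true parameters
#' r = 70% and T = 0.1 nM, a nine-value KD axis spanning four orders of
#' magnitude, kinetics frozen at t = 1200 min with the representative
#' kon = 0.0001444 nM^-1 min^-1, the default noise model, n = 25
#' replicate pseudo-experiments of triplicate wells, and exclusion
#' thresholds \{none, 1.25, 2.5, 5\} nM.
#'
#' @param params A [binding_parameters()] (its `kd` is superseded by
#'   `kd_axis`).
#' @param kd_axis KD axis (nM).
#' @param kinetics A [kinetic_settings()] (scenario and time included).
#' @param noise A [noise_model()].
#' @param n_replicates Number of simulated pseudo-experiments (>= 1).
#' @param replicates_per_point Wells per point; the noise SD of a
#'   replicate-mean cell is the overall SD divided by its square root
#'   (default 3, triplicate).
#' @param seed Integer seed recorded in all outputs.
#' @param exclusions Exclusion thresholds (nM), 0 = none.
#' @param explicit_triplicates If `TRUE`, draw `replicates_per_point`
#'   values per cell at the full overall SD and average them, instead of
#'   one draw at SD/sqrt(n); the two are distributionally identical.
#' @param perturb_rate_factor Passed to the error model (see
#'   [sd_antigen_grid()]).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params = binding_parameters(r = 0.7, kd = 1,
                                                          t_total = 0.1),
                              kd_axis = c(0.01, 0.0316, 0.1, 0.316, 1,
                                          3.16, 10, 31.62, 100),
                              kinetics = kinetic_settings(),
                              noise = noise_model(),
                              n_replicates = 25,
                              replicates_per_point = 3,
                              seed = 1L,
                              exclusions = c(0, 1.25, 2.5, 5),
                              explicit_triplicates = FALSE,
                              perturb_rate_factor = TRUE) {
  stopifnot(inherits(params, "binding_parameters"),
            inherits(kinetics, "kinetic_settings"),
            inherits(noise, "noise_model"),
            n_replicates >= 1, replicates_per_point >= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(params = params, kd_axis = kd_axis, kinetics = kinetics,
                 noise = noise, n_replicates = as.integer(n_replicates),
                 replicates_per_point = as.integer(replicates_per_point),
                 seed = as.integer(seed), exclusions = exclusions,
                 explicit_triplicates = isTRUE(explicit_triplicates),
                 perturb_rate_factor = isTRUE(perturb_rate_factor)),
            class = "simulation_config")
}

# Deterministic per-(replicate, kd-row) substream seed, kept below 2^31 so
# excluding or reordering rows never shifts another row's draws.
substream_seed <- function(seed, replicate, row) {
  ((abs(seed) %% 1000003L) * 1009L + replicate * 9973L + row * 101L) %%
    2147483647L
}

# Mean grid and per-cell noise SD for the configured scenario.
simulation_moments <- function(config) {
  eb <- error_budget(config$params, config$kd_axis, config$kinetics,
                     noise = config$noise,
                     perturb_rate_factor = config$perturb_rate_factor)
  list(mean = eb$grid, sd = eb$overall)
}

#' Draw one noisy replicate grid
#'
#' Each cell of the kinetics-distorted mean grid receives Gaussian noise
#' with SD equal to the overall error-budget SD divided by the square root
#' of the per-point replication (a triplicate mean by default). Draws use
#' R's Mersenne-Twister generator with a dedicated substream per
#' (replicate, KD row), so the same `(seed, replicate_index)` always
#' reproduces the same grid. Negative draws are retained; downstream fits
#' handle them.
#'
#' @param config A [simulation_config()].
#' @param replicate_index Replicate number (1-based).
#' @param moments Optional precomputed [simulation_moments] (internal
#'   cache used by the study driver).
#' @return A `bf_grid` (unvalidated) of noisy bound fractions.
#' @export
simulate_replicate <- function(config, replicate_index,
                               moments = simulation_moments(config)) {
  stopifnot(inherits(config, "simulation_config"), replicate_index >= 1)
  mean_g <- moments$mean
  sd_g <- moments$sd / sqrt(config$replicates_per_point)
  n_ag <- length(mean_g$antigen)
  values <- mean_g$values
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  for (j in seq_along(mean_g$kd)) {
    set.seed(substream_seed(config$seed, replicate_index, j),
             kind = "Mersenne-Twister")
    if (config$explicit_triplicates) {
      draws <- matrix(stats::rnorm(n_ag * config$replicates_per_point,
                                   mean = rep(mean_g$values[j, ],
                                              config$replicates_per_point),
                                   sd = rep(moments$sd[j, ],
                                            config$replicates_per_point)),
                      nrow = config$replicates_per_point, byrow = TRUE)
      values[j, ] <- colMeans(draws)
    } else {
      values[j, ] <- stats::rnorm(n_ag, mean = mean_g$values[j, ],
                                  sd = sd_g[j, ])
    }
  }
  bf_grid(mean_g$kd, mean_g$antigen, values, validate = FALSE)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run the estimator comparison study
#'
#' For every replicate and KD row, fits both estimators at every exclusion
#' threshold (the same random draws are refit at each threshold, matching
#' the stepwise-deletion design) and summarises the estimates per
#' (KD, method, exclusion): mean and SD of r_hat and kd_hat over the
#' replicates, plus the count of flagged fits (non-converged, negative or
#' non-finite estimates). Individual fit failures are counted, never abort
#' the study. Flagged estimates are included in the means, as they would
#' be in a naive analysis; `mean_r_ok`/`sd_r_ok` summarise unflagged fits
#' only.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `irfa_summary` with columns `kd_nM`,
#'   `method`, `exclusion_nM`, `mean_r`, `sd_r`, `mean_kd`, `sd_kd`,
#'   `mean_r_ok`, `sd_r_ok`, `n_flagged`, `n_fits`; attributes `seed`,
#'   `scenario` and `config`.
#' @export
run_comparison_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  moments <- simulation_moments(config)
  fits <- replicate_fits(config, moments)
  summarise_fits(fits, config)
}

# Long table of all per-replicate fits.
replicate_fits <- function(config, moments,
                           drop_duplicate_top = FALSE) {
  rows <- vector("list",
                 config$n_replicates * length(config$kd_axis) *
                   2L * length(config$exclusions))
  k <- 0L
  for (i in seq_len(config$n_replicates)) {
    g <- simulate_replicate(config, i, moments)
    for (j in seq_along(config$kd_axis)) {
      pts <- data.frame(ag0 = g$antigen$nominal,
                        bound_fraction = g$values[j, ])
      if (drop_duplicate_top)
        pts <- pts[-nrow(pts), , drop = FALSE]
      for (m in c("hyperbola", "lindmo")) for (ex in config$exclusions) {
        f <- fit_points(pts, m, ex)
        k <- k + 1L
        rows[[k]] <- data.frame(
          replicate = i, kd_nM = config$kd_axis[j], method = m,
          exclusion_nM = ex, r_hat = f$r_hat, kd_hat = f$kd_hat,
          flagged = f$flagged)
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

summarise_fits <- function(fits, config) {
  key <- interaction(fits$kd_nM, fits$method, fits$exclusion_nM,
                     drop = TRUE)
  parts <- split(fits, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- !d$flagged & is.finite(d$r_hat)
    data.frame(
      kd_nM = d$kd_nM[1], method = d$method[1],
      exclusion_nM = d$exclusion_nM[1],
      mean_r = mean(d$r_hat), sd_r = stats::sd(d$r_hat),
      mean_kd = mean(d$kd_hat), sd_kd = stats::sd(d$kd_hat),
      mean_r_ok = if (any(ok)) mean(d$r_hat[ok]) else NA_real_,
      sd_r_ok = if (sum(ok) > 1) stats::sd(d$r_hat[ok]) else NA_real_,
      n_flagged = sum(d$flagged), n_fits = nrow(d))
  }))
  out <- out[order(out$method, out$exclusion_nM, out$kd_nM), ]
  rownames(out) <- NULL
  attr(out, "seed") <- config$seed
  attr(out, "scenario") <- config$kinetics$scenario
  attr(out, "config") <- config
  class(out) <- c("irfa_summary", "data.frame")
  out
}

#' Run the comparison across plate scenarios
#'
#' One [run_comparison_study()] per scenario. For the saturated scenarios
#' an additional summary drops the duplicate bound fraction at the
#' highest (saturated) applied antigen level before fitting, quantifying
#' the benefit of discarding the redundant top point.
#'
#' @param config A [simulation_config()]; its kinetic settings' scenario
#'   is overridden per run.
#' @param scenarios Subset of `c("unsaturated", "saturated",
#'   "saturated_desorbing")`.
#' @return A named list of `irfa_summary` objects; saturated scenarios
#'   gain a `<scenario>_drop_top` entry.
#' @export
run_scenario_suite <- function(config,
                               scenarios = c("unsaturated", "saturated",
                                             "saturated_desorbing")) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  out <- list()
  for (sc in scenarios) {
    cfg <- config
    cfg$kinetics$scenario <- sc
    out[[sc]] <- run_comparison_study(cfg)
    if (sc != "unsaturated") {
      moments <- simulation_moments(cfg)
      fits <- replicate_fits(cfg, moments, drop_duplicate_top = TRUE)
      out[[paste0(sc, "_drop_top")]] <- summarise_fits(fits, cfg)
    }
  }
  out
}

#' Export the data behind the graphical comparison
#'
#' Means and SDs of `n` simulated replicate grids (the plotted points and
#' error bars) together with sampled fitted curves for both estimators,
#' with and without the 5 nM exclusion, per KD row.
#'
#' @param config A [simulation_config()]; `n` overrides its replicate
#'   count.
#' @param n Number of replicate grids to average (default 10).
#' @param curve_points Number of antigen samples per fitted curve.
#' @param dir Optional directory; when given, `points.csv` and `fits.csv`
#'   are written there with metadata headers.
#' @return A list with data frames `points` (kd_nM, ag0_nM, mean_bf,
#'   sd_bf) and `curves` (kd_nM, method, exclusion_nM, flagged, ag0_nM,
#'   bound_fraction), plus `fit_table` of fitted parameters.
#' @export
export_graphical_dataset <- function(config, n = 10, curve_points = 60,
                                     dir = NULL) {
  cfg <- config
  cfg$n_replicates <- as.integer(n)
  moments <- simulation_moments(cfg)
  grids <- lapply(seq_len(n), function(i)
    simulate_replicate(cfg, i, moments))
  arr <- simplify2array(lapply(grids, function(g) g$values))
  mean_bf <- apply(arr, c(1, 2), mean)
  sd_bf <- apply(arr, c(1, 2), stats::sd)
  antigen <- moments$mean$antigen
  kd_axis <- cfg$kd_axis
  points <- data.frame(
    kd_nM = rep(kd_axis, times = length(antigen)),
    ag0_nM = rep(antigen$nominal, each = length(kd_axis)),
    mean_bf = as.vector(mean_bf), sd_bf = as.vector(sd_bf))
  ag_grid <- exp(seq(log(min(antigen$nominal)), log(max(antigen$nominal)),
                     length.out = curve_points))
  curves <- list()
  fit_rows <- list()
  for (j in seq_along(kd_axis)) {
    pts <- data.frame(ag0 = antigen$nominal, bound_fraction = mean_bf[j, ])
    for (m in c("hyperbola", "lindmo")) for (ex in c(0, 5)) {
      f <- fit_points(pts, m, ex)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        kd_nM = kd_axis[j], method = m, exclusion_nM = ex,
        r_hat = f$r_hat, kd_hat = f$kd_hat, flagged = f$flagged)
      bfc <- if (is.finite(f$r_hat) && is.finite(f$kd_hat))
        f$r_hat * ag_grid / (ag_grid + f$kd_hat) else rep(NA_real_,
                                                          curve_points)
      curves[[length(curves) + 1L]] <- data.frame(
        kd_nM = kd_axis[j], method = m, exclusion_nM = ex,
        flagged = f$flagged, ag0_nM = ag_grid, bound_fraction = bfc)
    }
  }
  out <- list(points = points, curves = do.call(rbind, curves),
              fit_table = do.call(rbind, fit_rows))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(seed = as.character(cfg$seed), n = as.character(n),
              scenario = cfg$kinetics$scenario)
    write_df_csv(out$points, file.path(dir, "points.csv"), meta)
    write_df_csv(out$curves, file.path(dir, "fits.csv"), meta)
  }
  out
}

write_df_csv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# irfa export", con)
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.irfa_summary <- function(x, digits = 3, ...) {
  cat(sprintf("IRFA simulation summary (scenario: %s, seed: %d)\n",
              attr(x, "scenario"), attr(x, "seed")))
  df <- as.data.frame(x)
  df$mean_r <- round(100 * df$mean_r)
  df$sd_r <- round(100 * df$sd_r)
  df$mean_kd <- signif(df$mean_kd, 3)
  df$sd_kd <- signif(df$sd_kd, 3)
  df$mean_r_ok <- round(100 * df$mean_r_ok)
  df$sd_r_ok <- round(100 * df$sd_r_ok)
  names(df)[names(df) == "mean_r"] <- "mean_r_pct"
  names(df)[names(df) == "sd_r"] <- "sd_r_pct"
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
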