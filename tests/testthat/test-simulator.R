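test_that("zero noise reduces the study to the deterministic fits", {
  cfg <- simulation_config(kd_axis = c(1, 3.16), n_replicates = 1,
                           noise = noise_model(0, 0, 0, 0), seed = 11)
  g <- simulate_replicate(cfg, 1)
  det <- scenario_grid(cfg$params, cfg$kd_axis, cfg$kinetics)
  expect_equal(g$values, det$values, tolerance = 1e-14)
  sm <- run_comparison_study(cfg)
  h1 <- sm[sm$method == "hyperbola" & sm$exclusion_nM == 0 &
             sm$kd_nM == 1, ]
  expect_equal(round(100 * h1$mean_r), 80)
  expect_equal(signif(h1$mean_kd, 3), 6.64)
  l1 <- sm[sm$method == "lindmo" & sm$exclusion_nM == 0 & sm$kd_nM == 1, ]
  expect_equal(round(100 * l1$mean_r), 158)
})

test_that("replicates are reproducible from (seed, index) and independent per row", {
  cfg <- simulation_config(n_replicates = 2, seed = 5)
  expect_identical(simulate_replicate(cfg, 1), simulate_replicate(cfg, 1))
  expect_false(identical(simulate_replicate(cfg, 1)$values,
                         simulate_replicate(cfg, 2)$values))
  # dropping a KD row does not shift the other rows' draws
  cfg_sub <- simulation_config(kd_axis = cfg$kd_axis[-3],
                               n_replicates = 2, seed = 5)
  g_full <- simulate_replicate(cfg, 1)
  g_sub <- simulate_replicate(cfg_sub, 1)
  expect_equal(g_sub$values[1:2, ], g_full$values[1:2, ])
  # the whole summary is bit-reproducible
  s1 <- run_comparison_study(simulation_config(kd_axis = c(0.1, 1),
                                               n_replicates = 5, seed = 3))
  s2 <- run_comparison_study(simulation_config(kd_axis = c(0.1, 1),
                                               n_replicates = 5, seed = 3))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("noise has the triplicate-mean scale of the error budget", {
  cfg <- simulation_config(kd_axis = 1, seed = 21, n_replicates = 1)
  moments <- irfa:::simulation_moments(cfg)
  draws <- vapply(1:4000, function(i)
    simulate_replicate(cfg, i, moments)$values[1, 4], numeric(1))
  m <- moments$mean$values[1, 4]
  s <- moments$sd[1, 4] / sqrt(3)
  expect_equal(mean(draws), m, tolerance = 3 * s / sqrt(4000) / m)
  expect_equal(stats::sd(draws), s, tolerance = 0.05)
  # ~95% inside the stated two-sigma band
  cover <- mean(abs(draws - m) <= 2 * s)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
  # explicit-triplicate mode is distributionally equivalent
  cfg3 <- cfg
  cfg3$explicit_triplicates <- TRUE
  draws3 <- vapply(1:2000, function(i)
    simulate_replicate(cfg3, i, moments)$values[1, 4], numeric(1))
  expect_equal(stats::sd(draws3), s, tolerance = 0.08)
})

test_that("hyperbola is unbiased at equilibrium with noise on", {
  cfg <- simulation_config(kinetics = kinetic_settings(time = Inf),
                           kd_axis = c(0.1, 1), seed = 13)
  sm <- run_comparison_study(cfg)
  h <- sm[sm$method == "hyperbola" & sm$exclusion_nM == 0, ]
  for (i in seq_len(nrow(h))) {
    se <- h$sd_r[i] / sqrt(h$n_fits[i])
    expect_lt(abs(h$mean_r[i] - 0.7), 2 * se + 1e-12)
  }
})

test_that("hyperbola beats unexcluded Lindmo in precision on every row", {
  cfg <- simulation_config(seed = 2)
  sm <- run_comparison_study(cfg)
  for (kd in cfg$kd_axis) {
    sd_h <- sm$sd_r[sm$method == "hyperbola" & sm$exclusion_nM == 0 &
                      sm$kd_nM == kd]
    sd_l <- sm$sd_r[sm$method == "lindmo" & sm$exclusion_nM == 0 &
                      sm$kd_nM == kd]
    expect_lte(sd_h, sd_l)
  }
})

test_that("scenario suite handles saturation and desorption", {
  cfg <- simulation_config(kd_axis = 1, n_replicates = 8, seed = 17)
  suite <- run_scenario_suite(cfg)
  expect_named(suite, c("unsaturated", "saturated", "saturated_drop_top",
                        "saturated_desorbing",
                        "saturated_desorbing_drop_top"))
  # unsaturated equals the plain study on the same config
  expect_identical(as.data.frame(suite$unsaturated),
                   as.data.frame(run_comparison_study(cfg)))
  # saturated grid really computes with coated 30 nM at the top levels
  cfg_sat <- cfg
  cfg_sat$kinetics$scenario <- "saturated"
  det <- scenario_grid(cfg$params, 1, cfg_sat$kinetics)
  expect_equal(det$values[1, 6], det$values[1, 7])
  expect_equal(det$antigen$coated[6:7], c(30, 30))
  # desorption drags the plateau: hyperbola mean r drops vs saturated
  r_sat <- suite$saturated
  r_des <- suite$saturated_desorbing
  h_sat <- r_sat$mean_r[r_sat$method == "hyperbola" &
                          r_sat$exclusion_nM == 0]
  h_des <- r_des$mean_r[r_des$method == "hyperbola" &
                          r_des$exclusion_nM == 0]
  expect_lt(h_des, h_sat)
  # dropping the duplicate top point uses one fewer observation
  expect_true(all(suite$saturated_drop_top$n_fits == 8))
})

test_that("graphical export carries points, error bars and fitted curves", {
  cfg <- simulation_config(kd_axis = c(1, 10), seed = 23)
  out <- export_graphical_dataset(cfg, n = 6, curve_points = 20)
  expect_equal(nrow(out$points), 2 * 7)
  expect_true(all(out$points$sd_bf >= 0))
  expect_equal(nrow(out$curves), 2 * 2 * 2 * 20)
  # error bars are the replicate SDs by construction
  moments <- irfa:::simulation_moments(cfg)
  grids <- lapply(1:6, function(i)
    simulate_replicate(cfg, i, moments)$values)
  man_sd <- apply(simplify2array(grids), c(1, 2), stats::sd)
  expect_equal(out$points$sd_bf, as.vector(man_sd))
  dir <- withr::local_tempdir()
  export_graphical_dataset(cfg, n = 3, curve_points = 5, dir = dir)
  expect_true(file.exists(file.path(dir, "points.csv")))
  expect_true(file.exists(file.path(dir, "fits.csv")))
})

test_that("unexcluded Lindmo misbehaves at high KD in the graphical set", {
  cfg <- simulation_config(seed = 29)
  out <- export_graphical_dataset(cfg, n = 10, curve_points = 5)
  bad <- out$fit_table[out$fit_table$method == "lindmo" &
                         out$fit_table$exclusion_nM == 0 &
                         out$fit_table$kd_nM > 3.16, ]
  expect_gt(sum(bad$flagged), 0)
})
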