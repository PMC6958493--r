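test_that("exact bound fraction matches limits and the fixed-point oracle", {
  p <- default_params()
  expect_identical(bound_fraction_exact(0, p), 0)
  # asymptote r at effectively infinite antigen
  expect_equal(bound_fraction_exact(1e9, p), 0.7, tolerance = 1e-6)
  # independent fixed-point oracle at a depleting condition
  expect_equal(bound_fraction_exact(1.25, p),
               oracle_bound_fraction(1.25, 0.7, 1, 0.1),
               tolerance = 1e-10)
  # a spread of conditions against the oracle
  for (kd in c(0.01, 1, 100)) for (ag0 in c(0.5, 5, 80)) {
    expect_equal(bound_fraction_exact(ag0, p, kd = kd),
                 oracle_bound_fraction(ag0, 0.7, kd, 0.1),
                 tolerance = 1e-9)
  }
})

test_that("exact bound fraction rejects invalid domains", {
  p <- default_params()
  expect_error(bound_fraction_exact(-1, p), ">= 0")
  expect_error(binding_parameters(t_total = 0), "> 0")
  expect_error(bound_fraction_exact(1, p, kd = -2), "> 0")
})

test_that("returned root satisfies the quadratic and the mass balance", {
  p <- default_params()
  set.seed(42)
  for (i in 1:50) {
    ag0 <- stats::runif(1, 0.01, 800) * p$t_total
    kd <- 10^stats::runif(1, -2, 2)
    x <- bound_fraction_exact(ag0, p, kd = kd)
    a <- ag0 / p$t_total
    resid <- x^2 - x * (kd / p$t_total + a + p$r) + p$r * a
    expect_lt(abs(resid), 1e-10 * max(1, a))
    # mass balance: B/T == r*(ag0 - B)/((ag0 - B) + kd)
    b <- x * p$t_total
    expect_equal(x, p$r * (ag0 - b) / ((ag0 - b) + kd), tolerance = 1e-10)
    # conservation: bound amount cannot exceed reactive antibody or antigen
    expect_lte(b, min(p$r * p$t_total, ag0) + 1e-12)
  }
})

test_that("exact model is bounded above by the hyperbola, equal as T -> 0", {
  ag <- default_ag()
  for (kd in default_kd_axis()) {
    exact <- bound_fraction_exact(ag, default_params(), kd = kd)
    hyp <- bound_fraction_hyperbola(ag, 0.7, kd)
    expect_true(all(exact <= hyp + 1e-12))
    tiny <- binding_parameters(r = 0.7, kd = kd, t_total = 1e-9)
    expect_equal(bound_fraction_exact(ag, tiny, kd = kd), hyp,
                 tolerance = 1e-8)
  }
})

test_that("exact bound fraction is monotone in ag0, r and kd", {
  ag <- sort(c(default_ag(), 0.1, 200))
  for (kd in c(0.1, 1, 10)) {
    v <- bound_fraction_exact(ag, default_params(), kd = kd)
    expect_true(all(diff(v) >= -1e-12))
  }
  rs <- seq(0.1, 1, by = 0.1)
  v_r <- vapply(rs, function(r)
    bound_fraction_exact(5, binding_parameters(r = r, kd = 1,
                                               t_total = 0.1)),
    numeric(1))
  expect_true(all(diff(v_r) >= -1e-12))
  kds <- c(0.01, 0.1, 1, 10, 100)
  v_k <- vapply(kds, function(kd)
    bound_fraction_exact(5, default_params(), kd = kd), numeric(1))
  expect_true(all(diff(v_k) <= 1e-12))
})

test_that("hyperbola model has its defining landmarks", {
  expect_equal(bound_fraction_hyperbola(1, 0.7, 1), 0.35)
  expect_equal(bound_fraction_hyperbola(10, 0.7, 1), 0.7 * 10 / 11)
  # ten-fold antigen excess over KD reaches 91% of r
  expect_equal(bound_fraction_hyperbola(10, 0.7, 1) / 0.7, 10 / 11,
               tolerance = 1e-12)
  expect_equal(round(10 / 11, 2), 0.91)
  expect_identical(bound_fraction_hyperbola(0, 0.7, 1), 0)
  expect_error(bound_fraction_hyperbola(1, 0.7, 0), "> 0")
})

test_that("lindmo transform is the double reciprocal and counts drops", {
  tp <- lindmo_transform(data.frame(ag0 = c(1, 2),
                                    bound_fraction = c(0.35, 0.5)))
  expect_equal(tp$inv_ag0, c(1, 0.5))
  expect_equal(tp$inv_bound_fraction, c(1 / 0.35, 2))
  expect_identical(attr(tp, "n_dropped"), 0L)
  expect_warning(
    tp2 <- lindmo_transform(data.frame(ag0 = c(1, 2, 3),
                                       bound_fraction = c(0.4, -0.1, 0))),
    "non-positive")
  expect_identical(attr(tp2, "n_dropped"), 2L)
  expect_equal(nrow(tp2), 1L)
})

test_that("exact hyperbola points transform to an exact line", {
  ag <- default_ag()
  pts <- data.frame(ag0 = ag,
                    bound_fraction = bound_fraction_hyperbola(ag, 0.7, 1))
  tp <- lindmo_transform(pts)
  fit <- stats::lm(inv_bound_fraction ~ inv_ag0, data = tp)
  expect_equal(unname(stats::coef(fit)[1]), 1 / 0.7, tolerance = 1e-10)
  expect_equal(unname(stats::coef(fit)[2]), 1 / 0.7, tolerance = 1e-10)
  expect_lt(max(abs(stats::resid(fit))), 1e-10)
})

test_that("ideal grid composes the exact model cell by cell", {
  p <- default_params()
  g <- ideal_grid(1, default_ag(), p)
  expect_s3_class(g, "bf_grid")
  expect_equal(g$values[1, 7], oracle_bound_fraction(80, 0.7, 1, 0.1),
               tolerance = 1e-9)
  # the exact value sits just below the hyperbola's 0.7*80/81 = 0.6914
  expect_equal(round(g$values[1, 7], 3), 0.691)
  # T -> 0: depletion vanishes, grid equals the hyperbola
  g0 <- ideal_grid(default_kd_axis(), default_ag(),
                   binding_parameters(r = 0.7, kd = 1, t_total = 1e-9))
  hyp <- t(sapply(default_kd_axis(), function(kd)
    bound_fraction_hyperbola(default_ag(), 0.7, kd)))
  expect_equal(unname(g0$values), unname(hyp), tolerance = 1e-6)
  # r = 0: nothing binds
  gz <- ideal_grid(c(1, 10), default_ag(),
                   binding_parameters(r = 0, kd = 1, t_total = 0.1))
  expect_true(all(gz$values == 0))
})

test_that("grid containers validate their invariants", {
  expect_error(bf_grid(1, c(1, 2), matrix(c(0.2, 1.4), 1)), "\\[0, 1\\]")
  expect_error(bf_grid(1, c(1, 2), matrix(c(0.5, 0.2), 1)),
               "non-decreasing")
  expect_error(antigen_series(c(2, 1)), "non-decreasing")
  expect_error(antigen_series(c(1, 1)), "duplicated")
  s <- antigen_series(c(1, 2, 4), coated = c(1, 2, 2))
  expect_length(s, 3L)
  df <- as.data.frame(ideal_grid(1, c(1, 2), default_params()))
  expect_named(df, c("kd_nM", "ag0_nM", "ag0_coated_nM", "bound_fraction"))
})

test_that("grid round-trips through long-format CSV", {
  g <- ideal_grid(c(0.1, 1), default_ag(), default_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path, meta = c(seed = "1"))
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$value, as.data.frame(g)$bound_fraction)
})
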