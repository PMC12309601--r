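test_that("apo fraction follows the Hill curve", {
  fit <- hill_fit(n = 2, cu_half = 3)
  expect_equal(hill_apo_fraction(3, fit), 0.5)
  expect_equal(hill_apo_fraction(0, fit), 1)
  cu <- c(0.1, 1, 3, 10, 100)
  f <- hill_apo_fraction(cu, fit)
  expect_true(all(diff(f) < 0))
  # independent algebra: f = Kd / (Kd + cu^n)
  expect_equal(f, fit$kd / (fit$kd + cu^2))
  expect_error(hill_apo_fraction(-1, fit), "nonnegative")
  expect_error(hill_fit(0, 1), "positive")
  expect_error(hill_fit(1, -2), "positive")
})

test_that("single-point inversion recovers the coefficient exactly", {
  fit <- hill_fit(n = 0.62, cu_half = 0.0938)
  for (cu in c(0.001, 0.01, 0.5, 5)) {
    f <- hill_apo_fraction(cu, fit)
    expect_equal(hill_coefficient_point(f, cu, fit$cu_half), 0.62)
  }
  expect_error(hill_coefficient_point(0.5, 1, 1), "indeterminate")
  expect_error(hill_coefficient_point(1.2, 1, 2), "between")
})

test_that("dynamic-range inversion matches its closed form", {
  # noncooperative: 81-fold range
  expect_equal(hill_from_dynamic_range(81, 1), 1)
  # strong positive cooperativity n = 4: threefold range
  expect_equal(hill_from_dynamic_range(3, 1), 4)
  expect_equal(81^(1 / 4), 3)
  # self-consistency with the curve itself
  fit <- hill_fit(n = 1.7, cu_half = 2)
  cu10 <- fit$cu_half * (1 / 0.1 - 1)^(1 / fit$n)
  cu90 <- fit$cu_half * (1 / 0.9 - 1)^(1 / fit$n)
  expect_equal(hill_apo_fraction(cu10, fit), 0.1)
  expect_equal(hill_apo_fraction(cu90, fit), 0.9)
  expect_equal(hill_from_dynamic_range(cu10, cu90), 1.7)
  expect_error(hill_from_dynamic_range(1, 2), "exceed 1")
})

test_that("published dynamic-range pair gives the MAC coefficient", {
  n <- hill_from_dynamic_range(3.1e-6, 2.8e-9)
  expect_equal(n, log(81) / log(3.1e-6 / 2.8e-9))
  expect_lt(abs(n - 0.62), 0.01)
})

test_that("dissociation constants from half-saturation match printed values", {
  expect_equal(signif(kd_from_half_saturation(9.7e-20, 0.62), 2), 1.6e-12)
  expect_equal(signif(kd_from_half_saturation(2.8e-18, 0.90), 2), 1.6e-16)
  # CUP: back-computed half-saturation from the printed Kd round-trips
  cu_half_cup <- (9.3e-19)^(1 / 1.1)
  expect_equal(signif(kd_from_half_saturation(cu_half_cup, 1.1), 2), 9.3e-19)
  expect_equal(hill_fit(1.1, cu_half_cup)$kd, 9.3e-19)
})

test_that("curve fitting recovers the generating coefficient", {
  fit <- hill_fit(n = 0.9, cu_half = 2.7)
  pts <- simulate_titration_points(fit, n_points = 25)
  est <- fit_hill_curve(pts, cu_half = 2.7)
  expect_equal(est$n, 0.9, tolerance = 1e-10)
  expect_equal(attr(est, "n_se"), 0, tolerance = 1e-8)
  # midpoint band and saturated tails are excluded
  expect_lt(attr(est, "n_points"), nrow(pts))
  expect_error(fit_hill_curve(pts[1:2, ], cu_half = 2.7), "at least 3")
})

test_that("recalibration anchor matches the printed factor", {
  anchor <- calibration_anchor()
  expect_equal(anchor$factor, 0.59e-6 / 6.1e-19)
  expect_equal(signif(anchor$factor, 2), 9.7e11)
  expect_error(calibration_anchor(0, 1), "positive")
})

test_that("recalibration rescales the axis but preserves coefficients", {
  anchor <- calibration_anchor()
  fit <- hill_fit(n = 0.62, cu_half = 9.7e-20)
  refit <- recalibrate_hill_fit(fit, anchor)
  expect_equal(refit$n, fit$n)
  expect_equal(refit$cu_half, 9.7e-20 * anchor$factor)
  # refitting recalibrated points gives the same coefficient to 1e-12
  pts <- simulate_titration_points(fit, n_points = 30)
  pts2 <- recalibrate_axis(pts, anchor)
  expect_equal(pts2$apo_fraction, pts$apo_fraction)
  est <- fit_hill_curve(pts2, cu_half = refit$cu_half)
  expect_equal(est$n, 0.62, tolerance = 1e-12)
})

test_that("default titration fits carry the recalibrated parameters", {
  fits <- default_hill_fits()
  expect_equal(fits$MAC$n, 0.62)
  expect_equal(fits$ACE$n, 0.90)
  expect_equal(fits$CUP$n, 1.1)
  # half-saturation on the labile-pool scale, uM
  expect_equal(fits$MAC$cu_half, 9.7e-20 * calibration_anchor()$factor * 1e6)
  expect_equal(signif(fits$MAC$cu_half, 3), 0.0938)
  expect_equal(signif(fits$ACE$cu_half, 4), 2.708)
})

test_that("noisy titration points stay in (0, 1) and are seed-reproducible", {
  fit <- hill_fit(n = 1.1, cu_half = 1)
  set.seed(42)
  a <- simulate_titration_points(fit, n_points = 50, noise_cv = 0.2)
  set.seed(42)
  b <- simulate_titration_points(fit, n_points = 50, noise_cv = 0.2)
  expect_identical(a, b)
  expect_true(all(a$apo_fraction > 0 & a$apo_fraction < 1))
})

test_that("titration points round-trip through the TSV schema", {
  pts <- simulate_titration_points(hill_fit(0.62, 9.7e-20), n_points = 12)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_titration_points(pts, path)
  back <- read_titration_points(path)
  expect_equal(back$ligand, pts$ligand)
  expect_equal(back$apo_fraction, pts$apo_fraction)
  bad <- tempfile(fileext = ".tsv")
  on.exit(unlink(bad), add = TRUE)
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_titration_points(bad), "expected columns")
})

test_that("shipped approximate fixtures refit to the printed coefficients", {
  for (spec in list(list(file = "titration-points-mac.tsv", n = 0.62,
                         cu_half = 9.7e-20),
                    list(file = "titration-points-ace.tsv", n = 0.90,
                         cu_half = 2.8e-18))) {
    path <- system.file("extdata", spec$file, package = "cuflux")
    expect_true(nzchar(path))
    pts <- read_titration_points(path)
    fit <- fit_hill_curve(pts, cu_half = spec$cu_half)
    # fixture points are rounded to 3 significant figures, hence the loose
    # tolerance relative to the exact-generation round trip
    expect_equal(fit$n, spec$n, tolerance = 0.01)
  }
})
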