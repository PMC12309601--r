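test_that("apparent constants invert the rate laws", {
  alpha <- cf_ref$alpha
  # dilution: k_apparent = rate / (C/C_ref) = alpha * C_ref at every condition
  for (cn in cf_comp) {
    dn <- cuflux:::dilution_name(cn)
    ks <- cf_kt$k_apparent[cf_kt$reaction == dn]
    expect_equal(ks, rep(alpha * cf_ref$concentrations[[cn]], 7))
  }
  # demetallation: 100x the holo dilution constant
  expect_equal(unique(round(cf_kt$k_apparent[cf_kt$reaction == "MMACR"], 12)),
               round(100 * alpha * cf_ref$concentrations[["MAC"]], 12))
  expect_error(
    apparent_rate_constant(cf_net, "MMACF", 0.1,
                           dplyr::mutate(cf_conds[1, ], aMAC = 0), cf_ref),
    "zero")
})

test_that("exponent-matched metallations have exactly invariant constants", {
  # the partition exponent equals the rate-law exponent, so the apparent
  # constant is condition-free by algebra, not by numerical accident
  for (rxn in c("MMACF", "MACEF")) {
    ks <- cf_kt$k_apparent[cf_kt$reaction == rxn]
    expect_lt(max(ks) / min(ks) - 1, 1e-10)
  }
})

test_that("study table classifies 21 invariant and 4 trending reactions", {
  expect_equal(sum(cf_cls$class == "invariant"), 21)
  expect_equal(sum(cf_cls$class == "trending"), 4)
  expect_setequal(cf_cls$reaction[cf_cls$class == "trending"],
                  c("BACUP", "MCUPF", "MOTHF", "CUIN2"))
  # trending spreads are well clear of the threshold
  expect_true(all(cf_cls$spread[cf_cls$class == "trending"] > 1))
})

test_that("classification rejects systematically decreasing series", {
  mk <- function(k) tibble::tibble(
    condition = c("MBCS", "M0", "M10", "M50", "M100", "M175", "M250"),
    reaction = "X", rate = 1, k_apparent = k)
  # smooth decline with the spread of a genuine trend: not trending
  dec <- classify_invariance(mk(c(1.8, 1.5, 1.25, 1.05, 0.9, 0.8, 0.7)))
  expect_equal(dec$class, "invariant")
  # rising with a noise dip well inside the drawdown tolerance: trending
  dip <- classify_invariance(mk(c(0.5, 0.7, 0.95, 0.9, 1.3, 1.6, 2.0)))
  expect_equal(dip$class, "trending")
  # rising but shallow (spread below threshold): invariant
  flat <- classify_invariance(mk(c(1.00, 1.02, 1.05, 1.08, 1.10, 1.12, 1.15)))
  expect_equal(flat$class, "invariant")
  # structural zeros may lead a trending series
  floored <- classify_invariance(mk(c(0, 0, 0.2, 0.5, 0.9, 1.4, 1.9)))
  expect_equal(floored$class, "trending")
  expect_error(classify_invariance(mk(1:7)[1:3, ]), "at least 5")
})

test_that("logistic factor behaves as a soft switch", {
  expect_equal(cuflux:::logistic_factor(5, 2, 2), 0.5)
  expect_equal(cuflux:::logistic_factor(5, 2, 1e6), 1)
  expect_lt(cuflux:::logistic_factor(5, 2, 0), 1e-4)
  # steeper sensitivity sharpens the switch around the setpoint
  shallow <- cuflux:::logistic_factor(1, 2, 2.5)
  steep <- cuflux:::logistic_factor(10, 2, 2.5)
  expect_gt(steep, shallow)
  # no overflow at extreme arguments
  expect_equal(cuflux:::logistic_factor(1000, 5, 0), 0)
  expect_error(logistic_apparent_k(cu_logistic(1, 1, 1), -1), "nonnegative")
  expect_error(cu_logistic(-1, 1, 1), "positive")
})

test_that("logistic fitting recovers generating parameters on clean data", {
  sen <- cf_conds$CU
  gen <- cu_logistic(2, sen_sp = 0.6, n_sens = 12)
  k <- logistic_apparent_k(gen, sen)
  est <- fit_logistic(k, sen)
  expect_equal(est$sen_sp, 0.6, tolerance = 1e-6)
  expect_equal(est$k_invariant, 2, tolerance = 1e-6)
  expect_equal(est$n_sens, 12, tolerance = 1e-4)
  expect_true(attr(est, "convergence"))
  expect_lt(attr(est, "rss"), 1e-12)
  # determinism under a fixed restart seed
  est2 <- fit_logistic(k, sen)
  expect_identical(unclass(est)[c("k_invariant", "sen_sp", "n_sens")],
                   unclass(est2)[c("k_invariant", "sen_sp", "n_sens")])
  expect_error(fit_logistic(k[1:3], sen[1:3]), "at least 4")
})

test_that("consolidated parameters cover all reactions with the right split", {
  expect_s3_class(cf_params, "cu_params")
  expect_equal(length(cf_params$k), 21)
  expect_setequal(names(cf_params$logistic),
                  c("BACUP", "MCUPF", "MOTHF", "CUIN2"))
  expect_equal(cf_params$logistic$CUIN2$sensor, "COPPER")
  expect_equal(cf_params$logistic$MCUPF$sensor, "CU")
  # invariant constants equal per-condition means
  expect_equal(cf_params$k[["BAMAC"]],
               mean(cf_kt$k_apparent[cf_kt$reaction == "BAMAC"]))
  expect_output(print(cf_params), "21 invariant")
})
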