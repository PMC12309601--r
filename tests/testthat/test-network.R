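test_that("canonical network has the expected shape", {
  expect_s3_class(cf_net, "cu_network")
  expect_equal(nrow(cf_net$components), 10)
  expect_equal(nrow(cf_net$reactions), 25)
  expect_equal(cf_net$components$name, cf_comp)
  classes <- table(cf_net$reactions$class)
  expect_equal(unname(classes[["first_order_dilution"]]), 10)
  expect_equal(unname(classes[["first_order_demetallation"]]), 4)
  expect_equal(unname(classes[["mass_action_metallation"]]), 4)
  expect_equal(unname(classes[["michaelis_menten_import"]]), 2)
  expect_equal(sum(classes[c("constant_biosynthesis", "catalyzed_biosynthesis")]), 5)
  sensors <- stats::setNames(cf_net$reactions$logistic_sensor,
                             cf_net$reactions$name)
  expect_equal(sort(names(sensors)[!is.na(sensors)]),
               c("BACUP", "CUIN2", "MCUPF", "MOTHF"))
  expect_equal(unname(sensors[c("BACUP", "MCUPF", "MOTHF", "CUIN2")]),
               c("CU", "CU", "CU", "COPPER"))
})

test_that("import parameters and metallation exponents are as published", {
  km <- stats::setNames(cf_net$reactions$km, cf_net$reactions$name)
  expect_equal(km[["CUIN1"]], 2)
  expect_equal(km[["CUIN2"]], 35)
  expo <- stats::setNames(cf_net$reactions$exponent, cf_net$reactions$name)
  expect_equal(expo[["MMACF"]], 0.62)
  expect_equal(expo[["MACEF"]], 0.90)
  expect_equal(expo[["MCUPF"]], 1.1)
  expect_equal(expo[["MOTHF"]], 1)
  expect_equal(build_canonical_network(oth_exponent = 0.8)$reactions$exponent[
    match("MOTHF", cf_net$reactions$name)], 0.8)
})

test_that("stoichiometric matrix is correct", {
  expect_equal(dim(cf_S), c(10, 25))
  # dilution block is a negated identity
  D <- cf_S[, cuflux:::dilution_name(cf_comp)]
  expect_equal(unname(D), -diag(10))
  # one metallation column in full
  expect_equal(cf_S[, "MMACF"],
               c(aMAC = -1, MAC = 1, aACE = 0, ACE = 0, aCUP = 0, CUP = 0,
                 aOTH = 0, OTH = 0, CTR = 0, CU = -4))
  expect_equal(cf_S[, "MCUPR"],
               c(aMAC = 0, MAC = 0, aACE = 0, ACE = 0, aCUP = 1, CUP = -1,
                 aOTH = 0, OTH = 0, CTR = 0, CU = 8))
  expect_equal(cf_S[, "CUIN1"], c(aMAC = 0, MAC = 0, aACE = 0, ACE = 0,
                                  aCUP = 0, CUP = 0, aOTH = 0, OTH = 0,
                                  CTR = 0, CU = 1))
  # independent full-rank check
  expect_equal(qr(cf_S)$rank, 10)
})

test_that("copper weight vector matches stoichiometries", {
  expect_equal(cu_weight_vector(cf_net),
               c(aMAC = 0, MAC = 4, aACE = 0, ACE = 4, aCUP = 0, CUP = 8,
                 aOTH = 0, OTH = 1, CTR = 0, CU = 1))
})

test_that("rate factors are all unity at the reference state (imports excepted)", {
  f <- cuflux:::rate_factors(cf_net, cf_ref$concentrations, 14, cf_ref)
  non_import <- setdiff(names(f), c("CUIN1", "CUIN2"))
  expect_equal(unname(f[non_import]), rep(1, length(non_import)))
  expect_equal(f[["CUIN1"]], 14 / (2 + 14))
  expect_equal(f[["CUIN2"]], 14 / (35 + 14))
})

test_that("rate factors scale as the rate laws prescribe", {
  st <- cf_ref$concentrations
  st[["CU"]] <- 2 * st[["CU"]]
  st[["aMAC"]] <- 3 * st[["aMAC"]]
  f <- cuflux:::rate_factors(cf_net, st, 14, cf_ref)
  expect_equal(f[["MMACF"]], 3 * 2^0.62)
  expect_equal(f[["MCUPF"]], 2^1.1)
  expect_equal(f[["BCTR"]], 3)
  expect_equal(f[["DCU"]], 2)
  expect_equal(f[["MMACR"]], 1)
  expect_error(cuflux:::rate_factors(cf_net, -st, 14, cf_ref), "negative")
})

test_that("evaluate_rate applies constant, factor and logistic", {
  k <- 0.5
  r_plain <- evaluate_rate(cf_net, "MMACF", k, cf_ref$concentrations, 14, cf_ref)
  expect_equal(r_plain, 0.5)
  lp <- cu_logistic(1, sen_sp = cf_ref$concentrations[["CU"]], n_sens = 3)
  r_log <- evaluate_rate(cf_net, "MCUPF", k, cf_ref$concentrations, 14, cf_ref,
                         logistic = lp)
  expect_equal(r_log, 0.25) # logistic factor is 1/2 at the setpoint
  expect_error(evaluate_rate(cf_net, "NOPE", k, cf_ref$concentrations, 14, cf_ref),
               "unknown reaction")
})

test_that("YAML serialization round-trips the network", {
  txt <- network_to_yaml(cf_net)
  back <- network_from_yaml(text = txt)
  expect_equal(back$components, cf_net$components)
  expect_equal(stoichiometric_matrix(back), cf_S)
  expect_equal(back$reactions$km, cf_net$reactions$km)
  expect_equal(back$reactions$exponent, cf_net$reactions$exponent)
  expect_equal(back$reactions$logistic_sensor, cf_net$reactions$logistic_sensor)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  network_to_yaml(cf_net, tmp)
  expect_equal(stoichiometric_matrix(network_from_yaml(tmp)), cf_S)
})

test_that("malformed networks are rejected", {
  txt <- network_to_yaml(cf_net)
  bad <- sub("aMAC", "aXYZ", txt, fixed = TRUE)
  expect_error(network_from_yaml(text = bad))
})
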