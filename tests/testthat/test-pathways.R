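test_that("null basis spans the kernel", {
  G <- null_basis(cf_S)
  expect_equal(ncol(G), 15)
  expect_lt(max(abs(cf_S %*% G)), 1e-9)
  expect_equal(qr(G)$rank, 15)
})

test_that("matrix rank agrees with an independent decomposition", {
  expect_equal(matrix_rank(cf_S), qr(cf_S)$rank)
  set.seed(7)
  for (i in 1:20) {
    r <- sample(2:6, 1)
    A <- matrix(stats::rnorm(r * 8), r) # random full-row-rank factor
    B <- matrix(stats::rnorm(r * 9), ncol = r)
    M <- B %*% A # rank r by construction (almost surely)
    expect_equal(matrix_rank(M), qr(M)$rank)
  }
})

test_that("nonnegative basis is nonnegative, kernel-spanning and normalized", {
  W <- nonnegative_pathway_basis(null_basis(cf_S), S = cf_S)
  expect_equal(dim(W), c(25, 15))
  expect_true(all(W >= 0))
  expect_lt(max(abs(cf_S %*% W)), 1e-8)
  expect_equal(qr(W)$rank, 15)
  expect_equal(unname(apply(W, 2, max)), rep(1, 15))
  expect_equal(colnames(W), paste0("BP", 1:15))
})

test_that("small network: enumeration oracle finds the known extreme rays", {
  rays <- enumerate_extreme_rays(mini_S)
  expect_equal(ncol(rays), 5)
  expect_lt(max(abs(mini_S %*% rays)), 1e-9)
  # the conv+exch futile cycle must be among them
  cycle <- c(in_A = 0, conv = 1, out_B = 0, out_A = 0, in_B = 0, exch = 1)
  found <- apply(rays, 2, function(r) isTRUE(all.equal(unname(r / max(r)),
                                                       unname(cycle[rownames(rays)]))))
  expect_true(any(found))
})

test_that("small network: nonnegative basis lies in the enumerated cone", {
  rays <- enumerate_extreme_rays(mini_S)
  W <- nonnegative_pathway_basis(null_basis(mini_S), S = mini_S)
  expect_equal(ncol(W), 4)
  for (j in seq_len(ncol(W))) expect_true(in_cone(W[, j], rays))
  for (j in seq_len(ncol(rays))) expect_true(in_span(rays[, j], W))
})

test_that("canonical cone: basis columns are conic combinations of extreme rays", {
  rays <- enumerate_extreme_rays(cf_S)
  expect_lt(max(abs(cf_S %*% rays)), 1e-8)
  expect_true(all(rays >= -1e-9))
  expect_equal(qr(rays)$rank, 15)
  W <- nonnegative_pathway_basis(null_basis(cf_S), S = cf_S)
  for (j in seq_len(ncol(W))) expect_true(in_cone(W[, j], rays))
  # and the basis spans every extreme ray linearly (same kernel)
  for (j in seq_len(ncol(rays))) expect_true(in_span(rays[, j], W))
})

test_that("basis construction is invariant to reaction order", {
  set.seed(11)
  perm <- sample(ncol(cf_S))
  Sp <- cf_S[, perm]
  Wp <- nonnegative_pathway_basis(null_basis(Sp), S = Sp)
  expect_true(all(Wp >= 0))
  expect_lt(max(abs(Sp %*% Wp)), 1e-8)
  expect_equal(qr(Wp)$rank, 15)
})

test_that("independent reactions are the dilutions, demetallations and second importer", {
  ind <- cuflux:::independent_reactions(cf_net)
  expect_equal(length(ind), 15)
  expect_setequal(ind, c(cuflux:::dilution_name(cf_comp),
                         "MMACR", "MACER", "MCUPR", "MOTHR", "CUIN2"))
  W <- nonnegative_pathway_basis(null_basis(cf_S), S = cf_S)
  A <- W[ind, ]
  expect_equal(qr(A)$rank, 15) # uniquely solvable assignment
})

test_that("independent rate assignment encodes the steady-state conventions", {
  profile <- cf_conds[cf_conds$condition == "M10", ]
  ind <- independent_rate_assignment(profile, 0.0033, cuin1_rate = 0.02)
  expect_equal(ind[["DMAC"]], 0.0033 * profile$MAC)
  expect_equal(ind[["DCU"]], 0.0033 * profile$CU)
  expect_equal(ind[["MMACR"]], 100 * ind[["DMAC"]])
  expect_equal(ind[["MOTHR"]], 100 * ind[["DOTH"]])
  expect_equal(ind[["CUIN2"]], 0.0033 * profile$total_cell_cu - 0.02)
  # overshooting importer is floored with a warning
  expect_warning(
    ind2 <- independent_rate_assignment(profile, 0.0033, cuin1_rate = 1),
    "flooring")
  expect_equal(ind2[["CUIN2"]], 0)
})

test_that("importer calibration carries the whole influx at the anchor", {
  cal <- calibrate_cuin1(cf_conds, cf_ref)
  mbcs <- cf_conds[cf_conds$condition == "MBCS", ]
  expect_equal(cal$rates$cuin1[cal$rates$condition == "MBCS"],
               0.0033 * mbcs$total_cell_cu)
  expect_equal(signif(0.0033 * mbcs$total_cell_cu, 2), 0.018)
  expect_true(all(cal$rates$cuin1 > 0))
  expect_error(calibrate_cuin1(cf_conds, cf_ref, anchor_condition = "M7"),
               "not found")
})

test_that("steady-state rates satisfy the closed-form identities", {
  alpha <- cf_ref$alpha
  for (cond in cf_conds$condition) {
    r <- cf_rate_table[cf_rate_table$condition == cond, ]
    rates <- stats::setNames(r$rate, r$reaction)
    p <- cf_conds[cf_conds$condition == cond, ]
    expect_equal(rates[["BAMAC"]], alpha * (p$aMAC + p$MAC))
    expect_equal(rates[["BAACE"]], alpha * (p$aACE + p$ACE))
    expect_equal(rates[["MMACF"]], 101 * alpha * p$MAC)
    expect_equal(rates[["MACEF"]], 101 * alpha * p$ACE)
    expect_equal(rates[["BCTR"]], alpha * p$CTR)
    expect_true(all(rates >= 0))
    bal <- verify_flow_balance(rates, cf_net, p, alpha)
    expect_true(bal$balanced)
  }
})

test_that("steady-state rate vectors lie in the kernel of S", {
  for (cond in cf_conds$condition) {
    r <- cf_rate_table[cf_rate_table$condition == cond, ]
    rates <- stats::setNames(r$rate, r$reaction)
    expect_lt(max(abs(cf_S[, names(rates)] %*% rates)), 1e-10)
  }
})

test_that("infeasible assignments are rejected", {
  W <- nonnegative_pathway_basis(null_basis(cf_S), S = cf_S)
  ind <- cuflux:::independent_reactions(cf_net)
  good <- stats::setNames(rep(1, 15), ind)
  bad <- good
  # a second-importer flux far above the dilution outflow forces CUIN1 < 0
  bad[["CUIN2"]] <- 1e6
  expect_error(solve_steady_state_rates(W, bad), "infeasible")
  expect_error(solve_steady_state_rates(W, good[1:3]))
})
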