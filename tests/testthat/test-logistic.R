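test_that("saturated logistic fit equals empirical log-odds contrasts", {
  # cell event proportions: control (0.30, 0.20), treatment (0.15, 0.25)
  tr <- make_cell_trial(100, matrix(c(30, 15, 20, 25), 2, 2))
  fit <- fit_logistic(tr)
  expect_true(fit$converged)
  b <- coef(fit)
  expect_equal(unname(b["(Intercept)"]), qlogis(0.30), tolerance = 1e-7)
  expect_equal(unname(b["component"]), qlogis(0.20) - qlogis(0.30),
               tolerance = 1e-7)
  expect_equal(unname(b["treatment"]), qlogis(0.15) - qlogis(0.30),
               tolerance = 1e-7)
  expect_equal(unname(b["treatment:component"]),
               qlogis(0.25) - qlogis(0.15) - qlogis(0.20) + qlogis(0.30),
               tolerance = 1e-7)
})

test_that("uniform frequency weights rescale standard errors only", {
  tr <- simulate_trial(base_spec(n = 300), seed = 31)
  f1 <- fit_logistic(tr)
  f2 <- fit_logistic(tr, weights = rep(2.5, nrow(tr)))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(sqrt(diag(vcov(f2))), sqrt(diag(vcov(f1))) / sqrt(2.5),
               tolerance = 1e-8)
})

test_that("logistic MLE matches a brute-force optimizer on small data", {
  tr <- simulate_trial(base_spec(n = 30, or2 = 1.2), seed = 36)
  fit <- fit_logistic(tr)
  oracle <- oracle_logistic(tr)
  expect_lt(max(abs(coef(fit) - oracle)), 1e-6)

  w <- rep(c(1, 2, 0.5), length.out = nrow(tr))
  fitw <- fit_logistic(tr, weights = w)
  oraclew <- oracle_logistic(tr, weights = w)
  expect_lt(max(abs(coef(fitw) - oraclew)), 1e-6)
})

test_that("ANOVA ICC estimator recovers known correlation structure", {
  # perfectly duplicated components: all between-cluster variance
  dup <- make_cell_trial(40, matrix(c(20, 20, 20, 20), 2, 2))
  expect_equal(estimate_icc_anova(dup), 1)

  p <- solve_component_probs(0.5, 1, 0.10)
  ind <- simulate_pairs(100000, p$p1, p$p2, 0, seed = 35)
  tr0 <- tibble::tibble(
    participant_id = rep(seq_len(100000), each = 2),
    arm = 0L, component = rep(c(0L, 1L), 100000),
    event = as.integer(as.vector(t(as.matrix(ind))))
  )
  expect_lt(abs(estimate_icc_anova(tr0)), 0.01)

  tr1 <- simulate_trial(base_spec(or1 = 1, or2 = 1, n = 100000), seed = 36)
  expect_lt(abs(estimate_icc_anova(tr1) - 0.10), 0.01)

  const <- make_cell_trial(10, matrix(c(10, 10, 10, 10), 2, 2))
  expect_error(estimate_icc_anova(const), "degenerate outcomes")
})

test_that("ICC weighting leaves coefficients and inflates SEs uniformly", {
  tr <- simulate_trial(base_spec(n = 1000), seed = 37)
  f0 <- fit_logistic(tr)
  fdd <- fit_weighted_dd(tr)
  rho <- fdd$extras$icc
  expect_gt(rho, 0)
  expect_equal(coef(fdd), coef(f0), tolerance = 1e-8)
  expect_equal(sqrt(diag(vcov(fdd))), sqrt(diag(vcov(f0))) * sqrt(1 + rho),
               tolerance = 1e-8)
})

test_that("Rao-Scott design effect tracks within-participant duplication", {
  # y_i1 = y_i2 always: totals are 0 or 2, variance doubles
  dup <- make_cell_trial(40, matrix(c(20, 20, 20, 20), 2, 2))
  frs <- fit_weighted_rs(dup)
  k <- 40
  expect_equal(frs$extras$vif, rep(2 * k / (k - 1), 2), tolerance = 1e-10)

  # independent components at scale: vif near 1, fit near unweighted
  tr <- simulate_trial(base_spec(or1 = 1, or2 = 1, n = 50000, icc = 0),
                       seed = 38)
  frs <- fit_weighted_rs(tr)
  expect_lt(max(abs(frs$extras$vif - 1)), 0.05)
  expect_equal(coef(frs), coef(fit_logistic(tr)), tolerance = 1e-8)

  allev <- make_cell_trial(10, matrix(c(10, 10, 10, 0), 2, 2))
  allev$event[allev$arm == 0] <- 1L
  expect_error(fit_weighted_rs(allev), "degenerate arm")
})

test_that("trial data validation names the offending record", {
  tr <- simulate_trial(base_spec(n = 10), seed = 39)
  bad <- tr
  bad$event[3] <- 2L
  expect_error(check_trial_data(bad), "row 3")
  expect_error(check_trial_data(tr[-2, ]), "incomplete cluster")
  dup <- tr
  dup$component[2] <- 0L
  expect_error(check_trial_data(dup), "duplicated \\(participant, component\\)")
  mixed <- tr
  mixed$arm[1] <- 1L
  expect_error(check_trial_data(mixed), "both arms")
})
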