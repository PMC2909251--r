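test_that("replicate bookkeeping is conserved and reproducible", {
  spec <- base_spec(n = 200, or2 = 1.2)
  r1 <- run_scenario(spec, models = c("gee", "independent"),
                     tests = c("interaction", "composite"),
                     n_reps = 10, seed = 9)
  expect_equal(nrow(r1), 3)  # 2 models x interaction + 1 collapsed composite
  expect_true(all(r1$n_converged <= r1$n_reps))
  expect_true(all(r1$n_reject <= r1$n_converged))
  expect_true(all(r1$power >= 0 & r1$power <= 1))
  expect_equal(r1$model[r1$test == "composite"], "collapsed")

  r2 <- run_scenario(spec, models = c("gee", "independent"),
                     tests = c("interaction", "composite"),
                     n_reps = 10, seed = 9)
  expect_identical(r1, r2)
  r3 <- run_scenario(spec, models = c("gee", "independent"),
                     tests = c("interaction", "composite"),
                     n_reps = 10, seed = 10)
  expect_false(identical(r1, r3))
})

test_that("the driver's fast path equals the public simulate-and-fit route", {
  spec <- base_spec(n = 400, or2 = 1.1)
  res <- run_scenario(spec, models = c("gee", "weighted_dd"),
                      n_reps = 5, seed = 77)
  set.seed(77)
  seeds <- sample.int(2147483646L, 5)
  rej_gee <- 0L
  rej_dd <- 0L
  for (s in seeds) {
    tr <- simulate_trial(spec, seed = s)
    rej_gee <- rej_gee + wald_test(fit_gee(tr), "interaction")$reject
    rej_dd <- rej_dd + wald_test(fit_weighted_dd(tr), "interaction")$reject
  }
  expect_equal(res$n_reject[res$model == "gee"], as.integer(rej_gee))
  expect_equal(res$n_reject[res$model == "weighted_dd"], as.integer(rej_dd))
  expect_equal(res$n_converged, c(5L, 5L))
})

test_that("scenario grids match the shipped table layouts", {
  g1 <- table1_grid()
  expect_equal(nrow(g1), 12)
  expect_equal(g1$or2, seq(0.65, 1.20, by = 0.05))
  expect_true(all(g1$or1 == 0.65 & g1$ratio == 1 & g1$n == 2000))

  g2 <- table2_grid()
  expect_equal(nrow(g2), 5)
  expect_setequal(round(g2$ratio, 6), round(c(1, 1 / 3, 1 / 5, 3, 5), 6))
  expect_true(all(g2$or1 == 0.65 & g2$or2 == 1.00))

  g3 <- table3_grid()
  expect_equal(nrow(g3), 33)
  expect_true(all(g3$or2 >= g3$or1))
  expect_equal(sum(g3$or1 == 0.70), 11)
  expect_true(all(g3$icc == 0.10 & g3$control_rate == 0.5))
})

test_that("table rendering pivots to the publication layout", {
  spec <- base_spec(n = 200, or2 = 1.2)
  res <- run_power_study(dplyr::bind_rows(base_spec(n = 200, or2 = 1.0),
                                          base_spec(n = 200, or2 = 1.2)),
                         models = c("gee", "independent"), n_reps = 5, seed = 1)
  wide <- render_power_table(res, layout = 1)
  expect_equal(nrow(wide), 2)
  expect_true(all(c("or2", "power_pct_gee", "power_pct_independent",
                    "mc_se_pct_gee") %in% names(wide)))
  expect_warning(render_power_table(res[-1, ], layout = 1), "missing")
  expect_error(render_power_table(res, layout = 4), "layout")
  expect_error(render_power_table(res, layout = 3), "single model")

  p <- plot_power_curves(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("heterogeneity power rises with OR2 under common random numbers", {
  specs <- dplyr::bind_rows(base_spec(or2 = 0.75), base_spec(or2 = 1.00),
                            base_spec(or2 = 1.20))
  res <- run_power_study(specs, models = "gee", n_reps = 200, seed = 2026)
  expect_true(all(diff(res$power) > 0))
})

test_that("every interaction test controls its size at the null scenario", {
  res <- run_scenario(base_spec(or1 = 0.65, or2 = 0.65),
                      models = c("independent", "weighted_dd", "weighted_rs",
                                 "gee", "random_effects"),
                      n_reps = 2000, seed = 99)
  expect_true(all(res$n_converged >= 0.99 * res$n_reps))
  expect_true(all(res$power >= 0.02 & res$power <= 0.07))
  # the weighted fits are the conservative ones, GEE the most liberal
  pw <- setNames(res$power, res$model)
  expect_lte(pw[["weighted_dd"]], pw[["gee"]])
})

test_that("component imbalance degrades heterogeneity power asymmetrically", {
  ratios <- c(1, 1 / 3, 1 / 5, 3, 5)
  specs <- dplyr::bind_rows(lapply(ratios, function(r)
    base_spec(or1 = 0.65, or2 = 1.00, ratio = r)))
  res <- run_power_study(specs, models = "gee", n_reps = 2000, seed = 314)
  pw <- setNames(res$power, c("1:1", "1:3", "1:5", "3:1", "5:1"))
  se <- setNames(res$mc_se, names(pw))
  tol <- function(a, b) 2 * sqrt(se[a]^2 + se[b]^2)
  # more imbalance, less power (both orientations)
  expect_gt(pw["1:1"] - pw["1:3"], -tol("1:1", "1:3"))
  expect_gt(pw["1:3"] - pw["1:5"], -tol("1:3", "1:5"))
  expect_gt(pw["1:1"] - pw["3:1"], -tol("1:1", "3:1"))
  expect_gt(pw["3:1"] - pw["5:1"], -tol("3:1", "5:1"))
  # power is higher when the heterogeneous (larger-OR) component is rarer
  expect_gt(pw["3:1"] - pw["1:3"], -tol("3:1", "1:3"))
})
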