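test_that("joint probability links Pearson correlation to the 2x2 cell", {
  expect_equal(joint_prob(0.5, 0.5, 0), 0.25)
  expect_equal(joint_prob(0.5, 0.5, 1), 0.50)
  # p^2 + rho p (1 - p) at the balanced solved marginal
  expect_equal(joint_prob(0.308132, 0.308132, 0.10), 0.1162640,
               tolerance = 1e-6)
  expect_error(joint_prob(0.9, 0.1, 0.9), "unattainable correlation")
  expect_error(joint_prob(0, 0.5, 0.1), "in \\(0, 1\\)")
})

test_that("odds-ratio transform moves a probability on the odds scale", {
  expect_equal(or_to_prob(0.5, 1.0), 0.5)
  expect_equal(or_to_prob(0.5, 0.65), 0.65 / 1.65)
  expect_equal(or_to_prob(0.308132, 0.65), 0.2244969, tolerance = 1e-6)
  expect_error(or_to_prob(0.5, -1), "positive")
})

test_that("component-probability solver hits the composite rate", {
  s <- solve_component_probs(0.75, 1, 0)
  expect_equal(s$p1, 0.5, tolerance = 1e-9)
  expect_equal(s$p2, 0.5, tolerance = 1e-9)

  # balanced case has a quadratic closed form:
  # (1 - rho) p^2 - (2 - rho) p + R = 0
  closed <- (1.9 - sqrt(1.9^2 - 4 * 0.9 * 0.5)) / (2 * 0.9)
  s <- solve_component_probs(0.5, 1, 0.10)
  expect_equal(s$p1, closed, tolerance = 1e-9)

  s <- solve_component_probs(0.5, 3, 0.10)
  expect_equal(s$p1 / s$p2, 3, tolerance = 1e-9)
  expect_equal(s$p1, 0.4355, tolerance = 1e-3)
  expect_equal(s$p2, 0.1452, tolerance = 1e-3)
})

test_that("solver round-trips the composite rate across the design grid", {
  for (R in c(0.3, 0.5, 0.7)) {
    for (r in c(0.2, 1 / 3, 1, 3, 5)) {
      for (rho in c(0, 0.05, 0.10, 0.20)) {
        s <- solve_component_probs(R, r, rho)
        back <- s$p1 + s$p2 - joint_prob(s$p1, s$p2, rho)
        expect_equal(back, R, tolerance = 1e-9)
        expect_equal(s$p1 / s$p2, r, tolerance = 1e-8)
        if (r == 1) {
          closed <- ((2 - rho) - sqrt((2 - rho)^2 - 4 * (1 - rho) * R)) /
            (2 * (1 - rho))
          expect_equal(s$p2, closed, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("arm designs apply component odds ratios on the margins", {
  null <- build_arm_designs(base_spec(or1 = 1, or2 = 1))
  expect_equal(null[1, -1], null[2, -1], ignore_attr = TRUE)

  a <- build_arm_designs(base_spec(or1 = 0.65, or2 = 0.65))
  expect_equal(a$p1[2], 0.2244969, tolerance = 1e-6)
  expect_equal(a$p2[2], 0.2244969, tolerance = 1e-6)
  expect_equal(a$composite_rate[2], 0.3811852, tolerance = 1e-6)
  expect_equal(a$composite_rate[1], 0.5, tolerance = 1e-9)

  b <- build_arm_designs(base_spec(or1 = 0.65, or2 = 1.00))
  expect_equal(b$composite_rate[2], 0.4441889, tolerance = 1e-6)

  # treatment composite rate is monotone in each component OR
  rates_or2 <- vapply(seq(0.65, 1.2, by = 0.05), function(o2)
    build_arm_designs(base_spec(or1 = 0.65, or2 = o2))$composite_rate[2],
    numeric(1))
  expect_true(all(diff(rates_or2) > 0))
  rates_or1 <- vapply(c(0.65, 0.70, 0.75, 1.0), function(o1)
    build_arm_designs(base_spec(or1 = o1, or2 = 1.0))$composite_rate[2],
    numeric(1))
  expect_true(all(diff(rates_or1) > 0))
})

test_that("continuity-corrected power is a level-respecting, monotone test", {
  expect_lte(cc_chisq_power(0.4, 0.4, 500), 0.05 + 1e-12)
  pows_n <- vapply(c(100, 400, 1000, 4000), function(n)
    cc_chisq_power(0.5, 0.43, n), numeric(1))
  expect_true(all(diff(pows_n) > 0))
  pows_d <- vapply(c(0.48, 0.45, 0.42, 0.39), function(p)
    cc_chisq_power(0.5, p, 1000), numeric(1))
  expect_true(all(diff(pows_d) > 0))
})

test_that("design report includes composite OR and analytic power", {
  rep <- design_report(base_spec(or1 = 0.65, or2 = 1.00))
  expect_equal(rep$composite_control, 0.5, tolerance = 1e-9)
  rt <- rep$composite_treatment
  expect_equal(rep$composite_or, (rt / (1 - rt)) / 1, tolerance = 1e-9)
  expect_gt(rep$design_power, 0.5)
})

test_that("ratio strings parse with the p1:p2 orientation", {
  expect_equal(parse_ratio("1:5"), 0.2)
  expect_equal(parse_ratio("3:1"), 3)
  expect_equal(parse_ratio(2.5), 2.5)
  expect_error(parse_ratio("1:5:2"), "expected 'a:b'")
  expect_error(parse_ratio("a:b"), "positive numbers")
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(scenario_spec(control_rate = 1.2), "in \\(0, 1\\)")
  expect_error(scenario_spec(icc = -0.2), "negative icc")
  expect_error(scenario_spec(or1 = 0), "positive")
  expect_silent(validate_scenario(scenario_spec(ratio = "1:3")))
})
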