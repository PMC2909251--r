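#' Specify a simulated composite-outcome trial scenario
#'
#' A scenario fixes the design of a two-arm trial whose primary outcome is a
#' two-component binary composite: total sample size, allocation, the control
#' arm composite event rate, the intracluster correlation `icc` between the two
#' component outcomes of one participant, the per-component treatment odds
#' ratios, and the balance ratio of the control-arm component marginal
#' probabilities.
#'
#' @param n Total number of participants across both arms.
#' @param allocation Treatment:control allocation ratio (1 means 1:1).
#' @param control_rate Composite (union) event probability in the control arm.
#' @param icc Pearson correlation between the two component outcomes within a
#'   participant; only nonnegative values are supported by the simulator.
#' @param or1,or2 Treatment odds ratios acting on the marginal odds of
#'   components 1 and 2.
#' @param ratio Balance ratio r = p1/p2 of the control-arm component marginal
#'   probabilities; may be given as a number or a string like `"1:5"`.
#' @param alpha Two-sided test level.
#'
#' @return A one-row tibble with the validated scenario parameters.
#' @examples
#' scenario_spec(or1 = 0.65, or2 = 1.00)
#' @export
scenario_spec <- function(n = 2000, allocation = 1, control_rate = 0.5,
                          icc = 0.10, or1 = 0.65, or2 = 0.65, ratio = 1,
                          alpha = 0.05) {
  if (is.character(ratio)) ratio <- parse_ratio(ratio)
  spec <- tibble(
    n = as.integer(n), allocation = as.numeric(allocation),
    control_rate = as.numeric(control_rate), icc = as.numeric(icc),
    or1 = as.numeric(or1), or2 = as.numeric(or2),
    ratio = as.numeric(ratio), alpha = as.numeric(alpha)
  )
  validate_scenario(spec)
  spec
}

validate_scenario <- function(spec) {
  stopifnot(is.data.frame(spec))
  needed <- c("n", "allocation", "control_rate", "icc", "or1", "or2",
              "ratio", "alpha")
  missing <- setdiff(needed, names(spec))
  if (length(missing) > 0)
    abort(paste0("scenario is missing fields: ", paste(missing, collapse = ", ")))
  with(spec, {
    if (any(n < 2)) abort("n must be at least 2")
    if (any(allocation <= 0)) abort("allocation ratio must be positive")
    if (any(control_rate <= 0 | control_rate >= 1))
      abort("control_rate must be in (0, 1)")
    if (any(icc < 0)) abort("negative icc is not supported by the shared-Poisson generator")
    if (any(icc >= 1)) abort("icc must be below 1")
    if (any(or1 <= 0) || any(or2 <= 0)) abort("odds ratios must be positive")
    if (any(ratio <= 0)) abort("balance ratio must be positive")
    if (any(alpha <= 0 | alpha >= 1)) abort("alpha must be in (0, 1)")
  })
  invisible(spec)
}

#' Joint success probability of two correlated Bernoulli variables
#'
#' Converts a Pearson correlation on the binary scale into the joint
#' probability that both events occur:
#' `p11 = p1 p2 + rho * sqrt(p1 (1 - p1) p2 (1 - p2))`.
#' The result must lie within the Frechet bounds
#' `max(0, p1 + p2 - 1) <= p11 <= min(p1, p2)`; correlations that push it
#' outside are unattainable for those marginals.
#'
#' @param p1,p2 Marginal event probabilities, in (0, 1).
#' @param rho Pearson correlation between the two indicators.
#' @return The joint probability that both events occur.
#' @examples
#' joint_prob(0.5, 0.5, 0)    # independent: 0.25
#' joint_prob(0.5, 0.5, 0.1)
#' @export
joint_prob <- function(p1, p2, rho) {
  if (any(p1 <= 0 | p1 >= 1) || any(p2 <= 0 | p2 >= 1))
    abort("marginal probabilities must be in (0, 1)")
  p11 <- p1 * p2 + rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  upper <- pmin(p1, p2)
  lower <- pmax(0, p1 + p2 - 1)
  eps <- 1e-12
  if (any(p11 > upper + eps))
    abort(sprintf(
      "unattainable correlation: joint probability %.6f exceeds the upper Frechet bound min(p1, p2) = %.6f",
      max(p11), upper[which.max(p11 - upper)]))
  if (any(p11 < lower - eps))
    abort(sprintf(
      "unattainable correlation: joint probability %.6f is below the lower Frechet bound max(0, p1 + p2 - 1) = %.6f",
      min(p11), lower[which.min(p11 - lower)]))
  pmin(pmax(p11, lower), upper)
}

#' Apply an odds ratio to an event probability
#'
#' @param p Baseline probability in (0, 1).
#' @param or Odds ratio (> 0) multiplying the odds of `p`.
#' @return The probability whose odds are `or` times the odds of `p`.
#' @examples
#' or_to_prob(0.5, 0.65)  # 0.65 / 1.65
#' @export
or_to_prob <- function(p, or) {
  if (any(p <= 0 | p >= 1)) abort("p must be in (0, 1)")
  if (any(or <= 0)) abort("odds ratio must be positive")
  plogis(qlogis(p) + log(or))
}

#' Solve control-arm component probabilities from the composite rate
#'
#' Recovers the two component marginal probabilities (p1, p2) with a fixed
#' ratio `p1 = ratio * p2` such that the composite (union) event rate equals
#' `R` under within-participant correlation `icc`:
#' `p1 + p2 - joint_prob(p1, p2, icc) = R`.
#'
#' @param R Target composite event rate in (0, 1).
#' @param ratio Ratio p1/p2 of the component marginals (number or `"a:b"`).
#' @param icc Within-participant correlation between the components.
#' @return A one-row tibble with columns `p1` and `p2`.
#' @examples
#' solve_component_probs(0.75, 1, 0)   # two independent coins: p = 0.5
#' solve_component_probs(0.50, 1, 0.10)
#' @export
solve_component_probs <- function(R, ratio, icc) {
  if (R <= 0 || R >= 1) abort("composite rate must be in (0, 1)")
  if (is.character(ratio)) ratio <- parse_ratio(ratio)
  if (ratio <= 0) abort("ratio must be positive")
  if (icc < 0) abort("negative icc is not supported")
  f <- function(p2) {
    p1 <- ratio * p2
    p1 + p2 - (p1 * p2 + icc * sqrt(p1 * (1 - p1) * p2 * (1 - p2))) - R
  }
  hi <- min(1, 1 / ratio) - 1e-9
  root <- tryCatch(
    uniroot(f, lower = 1e-12, upper = hi, tol = 1e-12),
    error = function(e) abort(paste0("infeasible design: ", conditionMessage(e)))
  )
  p2 <- root$root
  p1 <- ratio * p2
  if (abs(f(p2)) > 1e-9) abort("infeasible design: solver did not reach the target rate")
  # errors here if icc is unattainable at the solved marginals
  joint_prob(p1, p2, icc)
  tibble(p1 = p1, p2 = p2)
}

#' Per-arm event structure implied by a scenario
#'
#' Solves the control-arm component marginals from the composite rate and
#' balance ratio, applies the component odds ratios to get the treatment-arm
#' marginals, and re-applies the same within-participant correlation in both
#' arms to obtain joint and composite probabilities.
#'
#' @param spec A scenario, as returned by [scenario_spec()].
#' @return A tibble with one row per arm (`arm` 0 = control, 1 = treatment) and
#'   columns `p1`, `p2`, `p11`, `composite_rate`.
#' @examples
#' build_arm_designs(scenario_spec(or1 = 0.65, or2 = 1.00))
#' @export
build_arm_designs <- function(spec) {
  validate_scenario(spec)
  ctrl <- solve_component_probs(spec$control_rate, spec$ratio, spec$icc)
  t1 <- or_to_prob(ctrl$p1, spec$or1)
  t2 <- or_to_prob(ctrl$p2, spec$or2)
  p11 <- c(joint_prob(ctrl$p1, ctrl$p2, spec$icc), joint_prob(t1, t2, spec$icc))
  p1 <- c(ctrl$p1, t1)
  p2 <- c(ctrl$p2, t2)
  tibble(
    arm = c(0L, 1L), p1 = p1, p2 = p2, p11 = p11,
    composite_rate = p1 + p2 - p11
  )
}

#' Power of the continuity-corrected chi-square two-proportion test
#'
#' Normal approximation to the power of the two-sided continuity-corrected
#' (Yates) chi-square test of equal proportions. The effect size is reduced by
#' the continuity correction `(1/n1 + 1/n2)/2` and standardised by the pooled
#' binomial standard error `sqrt(pbar (1 - pbar) (1/n1 + 1/n2))`, matching the
#' pooled-variance form of the Pearson chi-square statistic; both rejection
#' tails are accumulated.
#'
#' @param p_control,p_treatment True event proportions in the two arms.
#' @param n_per_arm Number of participants per arm (equal allocation).
#' @param alpha Two-sided level.
#' @return The approximate power, in \[0, 1\].
#' @examples
#' cc_chisq_power(0.5, 0.75 / 1.75, 1000)  # about 0.88
#' cc_chisq_power(0.5, 0.70 / 1.70, 1000)  # about 0.97
#' @export
cc_chisq_power <- function(p_control, p_treatment, n_per_arm, alpha = 0.05) {
  if (any(c(p_control, p_treatment) <= 0) || any(c(p_control, p_treatment) >= 1))
    abort("proportions must be in (0, 1)")
  if (any(n_per_arm < 2)) abort("n_per_arm must be at least 2")
  inv_n <- 2 / n_per_arm
  delta <- pmax(0, abs(p_control - p_treatment) - inv_n / 2)
  pbar <- (p_control + p_treatment) / 2
  se <- sqrt(pbar * (1 - pbar) * inv_n)
  z <- delta / se
  zcrit <- qnorm(1 - alpha / 2)
  pmin(pmax(pnorm(z - zcrit) + pnorm(-z - zcrit), 0), 1)
}

#' Analytic design report for a scenario
#'
#' Collects the solved per-arm probabilities, the implied composite (union)
#' odds ratio, and the analytic continuity-corrected chi-square power for the
#' composite comparison at the scenario's sample size.
#'
#' @inheritParams build_arm_designs
#' @return A one-row tibble with the scenario parameters, per-arm composite
#'   rates, component probabilities, implied composite OR, and analytic power.
#' @export
design_report <- function(spec) {
  arms <- build_arm_designs(spec)
  rc <- arms$composite_rate[arms$arm == 0L]
  rt <- arms$composite_rate[arms$arm == 1L]
  n_t <- round(spec$n * spec$allocation / (1 + spec$allocation))
  n_c <- spec$n - n_t
  tibble(
    n = spec$n, control_rate = spec$control_rate, icc = spec$icc,
    or1 = spec$or1, or2 = spec$or2, ratio = spec$ratio, alpha = spec$alpha,
    p1_control = arms$p1[1], p2_control = arms$p2[1],
    p1_treatment = arms$p1[2], p2_treatment = arms$p2[2],
    composite_control = rc, composite_treatment = rt,
    composite_or = (rt / (1 - rt)) / (rc / (1 - rc)),
    design_power = cc_chisq_power(rc, rt, min(n_c, n_t), spec$alpha)
  )
}

#' Parse a balance-ratio string
#'
#' `"a:b"` is read with the p1:p2 orientation, so `"1:5"` gives 0.2.
#'
#' @param x A string `"a:b"` or a number.
#' @return The numeric ratio a/b.
#' @export
parse_ratio <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(sprintf("cannot parse ratio '%s'; expected 'a:b'", x))
  a <- suppressWarnings(as.numeric(parts[1]))
  b <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(a) || is.na(b) || a <= 0 || b <= 0)
    abort(sprintf("cannot parse ratio '%s'; both parts must be positive numbers", x))
  a / b
}
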