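#' Fit any of the composite-heterogeneity models
#'
#' Umbrella over the individual fitters, keyed by the model tags used
#' throughout the power study.
#'
#' @inheritParams fit_logistic
#' @param model One of `"independent"`, `"weighted_dd"`, `"weighted_rs"`,
#'   `"gee"`, `"random_effects"`.
#' @param interaction Include the treatment-by-component interaction term
#'   (the heterogeneity parameter)? Setting `FALSE` fits the main-effects
#'   model used for the composite treatment-effect test.
#' @param n_quadrature Gauss-Hermite nodes for the random-effects model.
#' @return A `comphet_fit` object.
#' @export
fit_component_model <- function(data,
                                model = c("independent", "weighted_dd",
                                          "weighted_rs", "gee",
                                          "random_effects"),
                                interaction = TRUE, n_quadrature = 15) {
  model <- match.arg(model)
  if (interaction) {
    return(switch(model,
      independent = fit_logistic(data),
      weighted_dd = fit_weighted_dd(data),
      weighted_rs = fit_weighted_rs(data),
      gee = fit_gee(data),
      random_effects = fit_re_logistic(data, n_quadrature = n_quadrature)
    ))
  }
  m <- trial_matrices(data, interaction = FALSE)
  fit <- switch(model,
    independent = {
      core <- logistic_core(m$X, m$y)
      new_comphet_fit("independent", core$beta, core$vcov, core$converged,
                      core$n_iter, nobs = length(m$y),
                      n_participants = m$n_participants, reason = core$reason)
    },
    weighted_dd = {
      rho <- estimate_icc_anova(data)
      core <- logistic_core(m$X, m$y, rep(1 / (1 + rho), length(m$y)))
      new_comphet_fit("weighted_dd", core$beta, core$vcov, core$converged,
                      core$n_iter, extras = list(icc = rho),
                      nobs = length(m$y), n_participants = m$n_participants,
                      reason = core$reason)
    },
    weighted_rs = abort("the Rao-Scott main-effects fit is not provided; use weighted_dd or gee"),
    gee = {
      core <- gee_core(m$X, m$y)
      new_comphet_fit("gee", core$beta, core$vcov, core$converged,
                      core$n_iter,
                      extras = list(working_corr = core$working_corr,
                                    working = "unstructured"),
                      nobs = length(m$y), n_participants = m$n_participants,
                      reason = core$reason)
    },
    random_effects = {
      core <- re_core(m$X, m$y, n_quadrature = n_quadrature)
      new_comphet_fit("random_effects", core$beta, core$vcov, core$converged,
                      core$n_iter,
                      extras = list(sigma2 = core$sigma2,
                                    boundary = core$boundary),
                      nobs = length(m$y), n_participants = m$n_participants,
                      reason = core$reason)
    }
  )
  fit
}

#' Wald test of a model term
#'
#' Two-sided normal-approximation Wald test `z = estimate / se` of a single
#' coefficient. The heterogeneity test of the composite outcome is the Wald
#' test of the `interaction` (treatment-by-component) term.
#'
#' @param fit A converged `comphet_fit`.
#' @param term `"interaction"`, `"treatment"`, or `"component"`.
#' @param alpha Two-sided level for the rejection flag.
#' @return A one-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `alpha`, `reject`.
#' @examples
#' trial <- simulate_trial(scenario_spec(n = 400, or2 = 1.2), seed = 1)
#' wald_test(fit_gee(trial), "interaction")
#' @export
wald_test <- function(fit, term = c("interaction", "treatment", "component"),
                      alpha = 0.05) {
  term <- match.arg(term)
  if (!isTRUE(fit$converged))
    abort(paste0("cannot test unconverged fit",
                 if (!is.null(fit$reason)) paste0(" (", fit$reason, ")")))
  name <- switch(term, interaction = "treatment:component",
                 treatment = "treatment", component = "component")
  if (!name %in% names(fit$coefficients))
    abort(sprintf("term '%s' is not in the fitted model", name))
  est <- unname(fit$coefficients[name])
  se <- sqrt(fit$vcov[name, name])
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  tibble(term = term, estimate = est, std.error = se, statistic = z,
         p.value = p, alpha = alpha, reject = p < alpha)
}

#' Test the main treatment effect on the composite outcome
#'
#' Three routes to the composite (whole-outcome) treatment test:
#' * `"collapsed_score"` (default) collapses each participant to the composite
#'   indicator `max(event over components)` and applies the two-proportion
#'   score test (Pearson chi-square without continuity correction) — the test
#'   whose power the shipped treatment-effect table tracks;
#' * `"collapsed_chisq"` is the same comparison with the Yates continuity
#'   correction, the convention used for design sizing;
#' * `"gee_no_interaction"` stays at component level: it refits the GEE with
#'   treatment and component terms only and Wald-tests the treatment
#'   coefficient (a common-odds-ratio test, typically more powerful than the
#'   collapsed tests because it uses both component outcomes).
#'
#' @inheritParams fit_logistic
#' @param method `"collapsed_score"`, `"collapsed_chisq"`, or
#'   `"gee_no_interaction"`.
#' @param alpha Two-sided level.
#' @return A one-row tibble in the same shape as [wald_test()]. For the
#'   collapsed tests the estimate is the (Haldane-corrected) collapsed log
#'   odds ratio and the statistic is the signed square root of the chi-square
#'   statistic.
#' @export
composite_main_effect_test <- function(data,
                                       method = c("collapsed_score",
                                                  "collapsed_chisq",
                                                  "gee_no_interaction"),
                                       alpha = 0.05) {
  method <- match.arg(method)
  if (method == "gee_no_interaction") {
    fit <- fit_component_model(data, "gee", interaction = FALSE)
    return(wald_test(fit, "treatment", alpha = alpha))
  }
  check_trial_data(data)
  composite <- tapply(data$event, data$participant_id, max)
  arm <- tapply(data$arm, data$participant_id, max)
  tab <- table(factor(arm, levels = 0:1), factor(composite, levels = 0:1))
  if (any(rowSums(tab) == 0)) abort("both arms are required")
  ht <- suppressWarnings(prop.test(tab[, c(2, 1)],
                                   correct = method == "collapsed_chisq"))
  pr <- (tab[, 2] + 0.5) / (rowSums(tab) + 1)  # Haldane-corrected log OR
  est <- unname(qlogis(pr[2]) - qlogis(pr[1]))
  z <- sign(est) * sqrt(unname(ht$statistic))
  tibble(term = "treatment", estimate = est, std.error = NA_real_,
         statistic = z, p.value = unname(ht$p.value), alpha = alpha,
         reject = ht$p.value < alpha)
}
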