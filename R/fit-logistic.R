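# Validation and design-matrix assembly shared by all fitters ----------------

#' Validate long-format composite trial data
#'
#' Checks the schema used throughout the package: columns `participant_id`,
#' `arm`, `component`, `event`; binary arm/component/event codes; exactly one
#' row per (participant, component) with both components present; and a
#' constant arm within participant.
#'
#' @param data A data frame of component-level trial records.
#' @return The data, invisibly, if valid; otherwise an error naming the
#'   offending rows or participants.
#' @export
check_trial_data <- function(data) {
  needed <- c("participant_id", "arm", "component", "event")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0)
    abort(paste0("trial data is missing columns: ", paste(missing, collapse = ", ")))
  for (col in c("arm", "component", "event")) {
    bad <- which(!(data[[col]] %in% c(0, 1)))
    if (length(bad) > 0)
      abort(sprintf("column '%s' must be 0/1 (row %d has value %s)",
                    col, bad[1], format(data[[col]][bad[1]])))
  }
  uid <- unique(data$participant_id)
  idx <- match(data$participant_id, uid)
  dup <- which(duplicated(idx * 2 + data$component))
  if (length(dup) > 0)
    abort(sprintf("duplicated (participant, component) pair at row %d (participant %s)",
                  dup[1], format(data$participant_id[dup[1]])))
  cnt <- tabulate(idx, nbins = length(uid))
  bad_id <- which(cnt != 2L)
  if (length(bad_id) > 0)
    abort(sprintf("incomplete cluster: participant %s does not have exactly one row per component",
                  format(uid[bad_id[1]])))
  ord <- order(idx, data$component)
  arm_o <- data$arm[ord]
  i1 <- seq(1L, length(arm_o), by = 2L)
  mixed <- which(arm_o[i1] != arm_o[i1 + 1L])
  if (length(mixed) > 0)
    abort(sprintf("participant %s appears in both arms", format(uid[mixed[1]])))
  invisible(data)
}

# Returns X, y, and cluster structure ordered by participant then component.
trial_matrices <- function(data, interaction = TRUE, validate = TRUE) {
  if (validate) check_trial_data(data)
  ord <- order(data$participant_id, data$component)
  x1 <- as.numeric(data$arm[ord])
  x2 <- as.numeric(data$component[ord])
  X <- if (interaction) {
    cbind("(Intercept)" = 1, treatment = x1, component = x2,
          "treatment:component" = x1 * x2)
  } else {
    cbind("(Intercept)" = 1, treatment = x1, component = x2)
  }
  list(X = X, y = as.numeric(data$event[ord]),
       id = data$participant_id[ord], n_participants = nrow(data) / 2)
}

# Fit object ------------------------------------------------------------------

new_comphet_fit <- function(model, coefficients, vcov, converged, n_iter,
                            extras = list(), nobs = NA_integer_,
                            n_participants = NA_integer_, reason = NULL) {
  structure(
    list(model = model, coefficients = coefficients, vcov = vcov,
         converged = converged, n_iter = n_iter, extras = extras,
         nobs = nobs, n_participants = n_participants, reason = reason),
    class = "comphet_fit"
  )
}

#' @export
print.comphet_fit <- function(x, ...) {
  cat("<comphet_fit>", x$model,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  print(round(x$coefficients, 4))
  ex <- x$extras[vapply(x$extras, is.numeric, logical(1))]
  if (length(ex) > 0)
    cat("  extras:", paste(names(ex), signif(unlist(ex), 4), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.comphet_fit <- function(object, ...) object$coefficients

#' @export
vcov.comphet_fit <- function(object, ...) object$vcov

#' Tidy a composite-model fit
#'
#' @param x A `comphet_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.comphet_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  z <- x$coefficients / se
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' One-row summary of a composite-model fit
#'
#' @param x A `comphet_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the model tag, convergence flag, iteration
#'   count, and model-specific extras (estimated ICC, working correlation, or
#'   random-intercept variance where applicable).
#' @export
glance.comphet_fit <- function(x, ...) {
  tibble(
    model = x$model, converged = x$converged, n_iter = x$n_iter,
    nobs = x$nobs, n_participants = x$n_participants,
    icc = x$extras$icc %||% NA_real_,
    working_corr = x$extras$working_corr %||% NA_real_,
    sigma2 = x$extras$sigma2 %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted Bernoulli maximum likelihood via IRLS (stats::glm.fit); weights are
# frequency-type, so the covariance is the inverse Fisher information of the
# weighted likelihood.
logistic_core <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  fit <- suppressWarnings(glm.fit(
    x = X, y = y, weights = w, family = binomial(),
    control = list(epsilon = 1e-12, maxit = 100)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  converged <- isTRUE(fit$converged) && all(is.finite(beta)) &&
    max(abs(beta)) < 15
  info <- crossprod(X, w * mu * (1 - mu) * X)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) {
    converged <- FALSE
    vc <- matrix(NA_real_, ncol(X), ncol(X))
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = setNames(beta, colnames(X)), vcov = vc,
       converged = converged, n_iter = fit$iter,
       reason = if (converged) NULL else "IRLS did not converge (possible separation)")
}

#' Logistic regression ignoring within-participant correlation
#'
#' Fits `logit P(event) = b0 + b1 treatment + b2 component +
#' b3 treatment x component` by maximum likelihood, treating all component
#' rows as independent. Optional positive weights are treated as frequency
#' weights.
#'
#' @param data Long-format trial data (see [check_trial_data()]).
#' @param weights Optional positive per-row weights, in the row order of
#'   `data`.
#' @return A `comphet_fit` object.
#' @examples
#' trial <- simulate_trial(scenario_spec(n = 400), seed = 1)
#' tidy(fit_logistic(trial))
#' @export
fit_logistic <- function(data, weights = NULL) {
  m <- trial_matrices(data)
  if (!is.null(weights)) {
    if (length(weights) != nrow(data) || any(weights <= 0))
      abort("weights must be positive and match the number of rows")
    ord <- order(data$participant_id, data$component)
    weights <- as.numeric(weights)[ord]
  }
  core <- logistic_core(m$X, m$y, weights)
  new_comphet_fit("independent", core$beta, core$vcov, core$converged,
                  core$n_iter, extras = list(),
                  nobs = length(m$y), n_participants = m$n_participants,
                  reason = core$reason)
}

#' ANOVA estimator of the within-participant intracluster correlation
#'
#' One-way analysis of variance over participants (clusters of the two
#' component outcomes, cluster size m = 2):
#' `rho = (MSB - MSW) / (MSB + (m - 1) MSW)`, truncated to \[-1, 1\].
#' The estimator assumes a common mean across the cluster members, so with
#' components of very different prevalence the prevalence gap inflates the
#' within-cluster mean square and the estimate can be negative even when the
#' underlying correlation is positive; the weighted fits rely on exactly this
#' behaviour to correct for the resulting under-dispersion.
#'
#' @inheritParams fit_logistic
#' @return The estimated ICC, a single number in \[0, 1\].
#' @export
estimate_icc_anova <- function(data) {
  m <- trial_matrices(data)
  icc_core(m$y)
}

# y ordered as participant pairs; one-way ANOVA ICC with cluster size 2
icc_core <- function(y) {
  k <- length(y) / 2L
  if (k < 2) abort("at least 2 participants are required")
  i1 <- seq(1L, length(y), by = 2L)
  ybar_i <- (y[i1] + y[i1 + 1L]) / 2
  gbar <- mean(y)
  msb <- 2 * sum((ybar_i - gbar)^2) / (k - 1)
  msw <- sum((y - rep(ybar_i, each = 2L))^2) / k
  if (msb + msw == 0) abort("degenerate outcomes: no variance in events")
  min(max((msb - msw) / (msb + msw), -1), 1)
}

#' ICC-weighted logistic regression (Donald-Donner weights)
#'
#' Estimates the within-participant ICC by [estimate_icc_anova()] and fits the
#' interaction logistic model with every row downweighted by the common
#' cluster design effect, `w = 1 / (1 + (m - 1) rho)` with m = 2.
#'
#' @inheritParams fit_logistic
#' @return A `comphet_fit` with `extras$icc` and `extras$weight`.
#' @export
fit_weighted_dd <- function(data) {
  rho <- estimate_icc_anova(data)
  if (rho <= -0.99) abort("ICC estimate at its lower bound; weights undefined")
  w <- 1 / (1 + rho)
  fit <- fit_logistic(data, weights = rep(w, nrow(data)))
  fit$model <- "weighted_dd"
  fit$extras <- list(icc = rho, weight = w)
  fit
}

#' Design-effect weighted logistic regression (Rao-Scott weights)
#'
#' Estimates a per-arm variance inflation factor (design effect) as the ratio
#' of the empirical variance of participant-level event totals to the binomial
#' variance, and fits the interaction logistic model with rows in arm j
#' weighted `1 / vif_j`. Positive within-participant correlation gives
#' `vif > 1` (downweighting); unequal component prevalences push the ratio
#' below 1 (cluster totals are under-dispersed relative to a common-p
#' binomial), and the resulting weights above 1 sharpen the fit accordingly.
#'
#' @inheritParams fit_logistic
#' @return A `comphet_fit` with `extras$vif` (length-2, control then
#'   treatment).
#' @export
fit_weighted_rs <- function(data) {
  m <- trial_matrices(data)
  core <- rs_core(m$X, m$y)
  new_comphet_fit("weighted_rs", core$beta, core$vcov, core$converged,
                  core$n_iter, extras = list(vif = core$vif),
                  nobs = length(m$y), n_participants = m$n_participants,
                  reason = core$reason)
}

rs_core <- function(X, y) {
  i1 <- seq(1L, length(y), by = 2L)
  arm_i <- X[i1, "treatment"]
  totals <- y[i1] + y[i1 + 1L]
  vif <- numeric(2)
  w_row <- numeric(length(y))
  for (j in 0:1) {
    sel <- arm_i == j
    kj <- sum(sel)
    pj <- sum(totals[sel]) / (2 * kj)
    if (pj <= 0 || pj >= 1) abort(sprintf("degenerate arm: arm %d has event proportion %g", j, pj))
    v <- (kj / ((kj - 1) * 2 * kj)) * sum((totals[sel] - 2 * pj)^2) / (pj * (1 - pj))
    vif[j + 1] <- max(v, 0.05)  # guard against a degenerate zero ratio
    w_row[rep(sel, each = 2L)] <- 1 / vif[j + 1]
  }
  core <- logistic_core(X, y, w_row)
  core$vif <- vif
  core
}
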