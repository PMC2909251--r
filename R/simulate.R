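#' Shared-Poisson parameters for a correlated binary pair
#'
#' The generator draws three independent Poisson counts
#' `X1 ~ Pois(lambda1)`, `X2 ~ Pois(lambda2)`, `X12 ~ Pois(alpha12)` and forms
#' `Z1 = X1 + X12`, `Z2 = X2 + X12`; the binary events are the zero-count
#' indicators `Yk = 1(Zk = 0)`, so `P(Yk = 1) = exp(-(lambdak + alpha12))`.
#' Given target marginals `p1`, `p2` and correlation `rho`, the shared rate is
#' `alpha12 = log(1 + rho sqrt(p1 q1 p2 q2) / (p1 p2))` and the
#' component-specific rates are `-log(pk) - alpha12`.
#'
#' @param p1,p2 Target marginal event probabilities, in (0, 1].
#' @param rho Target nonnegative Pearson correlation between the events.
#' @return A list with `lambda1`, `lambda2`, `alpha12`.
#' @examples
#' park_params(0.5, 0.5, 0)    # independence: alpha12 = 0
#' park_params(0.5, 0.5, 0.5)  # alpha12 = log(1.5)
#' @export
park_params <- function(p1, p2, rho) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    abort("marginal probabilities must be in (0, 1]")
  if (rho < 0) abort("negative correlation is not representable with shared Poisson components")
  t1 <- -log(p1)
  t2 <- -log(p2)
  a12 <- log(1 + rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2)) / (p1 * p2))
  if (a12 > min(t1, t2) + 1e-12)
    abort(sprintf(
      "unattainable correlation: shared rate %.6f exceeds a total rate (-log p = %.6f)",
      a12, min(t1, t2)))
  list(lambda1 = max(t1 - a12, 0), lambda2 = max(t2 - a12, 0), alpha12 = a12)
}

# Fast path: n x 2 integer matrix of correlated Bernoulli outcomes.
# Poisson counts are generated by inversion (qpois of uniforms) so that runs
# sharing a seed across scenarios are monotonically coupled (common random
# numbers).
sim_pairs_matrix <- function(n, p1, p2, rho) {
  par <- park_params(p1, p2, rho)
  u <- matrix(runif(3L * n), n, 3L)
  shared <- qpois(u[, 1L], par$alpha12)
  z1 <- qpois(u[, 2L], par$lambda1) + shared
  z2 <- qpois(u[, 3L], par$lambda2) + shared
  cbind(y1 = as.integer(z1 == 0L), y2 = as.integer(z2 == 0L))
}

#' Simulate correlated binary outcome pairs
#'
#' Draws `n` independent participants, each with two correlated binary
#' component outcomes generated by the shared-Poisson-component construction
#' (see [park_params()]).
#'
#' @param n Number of participants.
#' @param p1,p2 Marginal event probabilities.
#' @param rho Nonnegative within-participant correlation.
#' @param seed Optional integer seed set before drawing.
#' @return A tibble with columns `y1`, `y2` (0/1), one row per participant.
#' @examples
#' simulate_pairs(5, 0.5, 0.5, 0.1, seed = 1)
#' @export
simulate_pairs <- function(n, p1, p2, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_tibble(as.data.frame(sim_pairs_matrix(n, p1, p2, rho)))
}

#' Simulate a composite-outcome trial
#'
#' Generates long-format component-level data for a two-arm trial under a
#' scenario: the control-arm component marginals are solved from the composite
#' rate and balance ratio, the treatment arm applies the component odds
#' ratios, and both arms share the within-participant correlation `icc`.
#' Each participant contributes one row per component.
#'
#' @param spec A scenario from [scenario_spec()].
#' @param seed Optional integer seed; a given (spec, seed) pair always yields
#'   the identical dataset.
#' @return A tibble with columns `participant_id`, `arm` (0 control /
#'   1 treatment), `component` (0/1), `event` (0/1), ordered by participant
#'   then component. Control participants come first.
#' @examples
#' trial <- simulate_trial(scenario_spec(n = 200, or1 = 0.65, or2 = 1.0), seed = 7)
#' dplyr::count(trial, arm, component, event)
#' @export
simulate_trial <- function(spec, seed = NULL) {
  validate_scenario(spec)
  if (!is.null(seed)) set.seed(seed)
  arms <- build_arm_designs(spec)
  n_t <- as.integer(round(spec$n * spec$allocation / (1 + spec$allocation)))
  n_c <- as.integer(spec$n) - n_t
  yc <- sim_pairs_matrix(n_c, arms$p1[1], arms$p2[1], spec$icc)
  yt <- sim_pairs_matrix(n_t, arms$p1[2], arms$p2[2], spec$icc)
  n <- n_c + n_t
  tibble(
    participant_id = rep(seq_len(n), each = 2L),
    arm = rep(c(0L, 1L), times = c(2L * n_c, 2L * n_t)),
    component = rep(c(0L, 1L), times = n),
    event = as.integer(rbind(
      matrix(t(yc), ncol = 1L),
      matrix(t(yt), ncol = 1L)
    ))
  )
}
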