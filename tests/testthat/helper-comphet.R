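# Shared fixtures and independent oracles for the test suite.

base_spec <- function(or1 = 0.65, or2 = 0.65, ratio = 1, n = 2000,
                      icc = 0.10) {
  scenario_spec(n = n, control_rate = 0.5, icc = icc, or1 = or1, or2 = or2,
                ratio = ratio, alpha = 0.05)
}

# Deterministic trial built from per-cell event counts: `events[arm, comp]`
# participants with an event on that component, out of `n_per_arm` per arm.
# Events are assigned to the lowest-numbered participants of the arm, so the
# within-participant pairing is fixed and reproducible.
make_cell_trial <- function(n_per_arm, events) {
  stopifnot(all(dim(events) == c(2, 2)), all(events <= n_per_arm))
  rows <- list()
  pid <- 0L
  for (a in 0:1) {
    for (i in seq_len(n_per_arm)) {
      pid <- pid + 1L
      rows[[pid]] <- data.frame(
        participant_id = pid, arm = a, component = c(0L, 1L),
        event = c(as.integer(i <= events[a + 1, 1]),
                  as.integer(i <= events[a + 1, 2]))
      )
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Brute-force weighted Bernoulli ML: direct Nelder-Mead maximization of the
# log-likelihood, independent of the IRLS route under test.
oracle_logistic <- function(data, weights = NULL, interaction = TRUE) {
  ord <- order(data$participant_id, data$component)
  x1 <- data$arm[ord]
  x2 <- data$component[ord]
  y <- data$event[ord]
  X <- if (interaction) cbind(1, x1, x2, x1 * x2) else cbind(1, x1, x2)
  w <- if (is.null(weights)) rep(1, length(y)) else weights[ord]
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
               control = list(reltol = 3e-16, maxit = 50000))
  opt <- optim(opt$par, nll, method = "Nelder-Mead",
               control = list(reltol = 3e-16, maxit = 50000))
  opt$par
}

# Marginal log-likelihood of the random-intercept logistic model by dense
# Simpson-rule integration over the random effect (no quadrature tricks).
oracle_re_loglik <- function(data, beta, sigma, lim = 8, step = 0.002) {
  ord <- order(data$participant_id, data$component)
  x1 <- data$arm[ord]
  x2 <- data$component[ord]
  y <- data$event[ord]
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + beta[4] * x1 * x2
  b <- seq(-lim * sigma, lim * sigma, by = step * sigma)
  if (length(b) %% 2 == 0) b <- b[-length(b)]
  w <- rep(c(2, 4), length.out = length(b))
  w[1] <- w[length(b)] <- 1
  w <- w / 3
  phi <- exp(-b^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  i1 <- seq(1, length(y), by = 2)
  ll <- 0
  for (i in i1) {
    e1 <- eta[i] + b
    e2 <- eta[i + 1] + b
    f <- plogis(e1)^y[i] * (1 - plogis(e1))^(1 - y[i]) *
      plogis(e2)^y[i + 1] * (1 - plogis(e2))^(1 - y[i + 1]) * phi
    ll <- ll + log(sum(w * f) * step * sigma)
  }
  ll
}

oracle_re_fit <- function(data, start) {
  nll <- function(par) -oracle_re_loglik(data, par[1:4], exp(par[5]),
                                         step = 0.001)
  num_grad <- function(par, h = 1e-6) {
    vapply(seq_along(par), function(j) {
      e <- replace(numeric(length(par)), j, h)
      (nll(par + e) - nll(par - e)) / (2 * h)
    }, numeric(1))
  }
  par <- c(start[1:4], log(start[5]))
  par <- optim(par, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 20000))$par
  par <- optim(par, nll, gr = num_grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
  c(par[1:4], sigma = exp(par[5]))
}
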