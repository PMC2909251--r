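# Random-intercept logistic regression fitted by maximizing the marginal
# likelihood, with the participant effect integrated out by adaptive
# Gauss-Hermite quadrature. Clusters sharing a (covariate, outcome) pattern
# contribute identical likelihood terms, so clusters are collapsed to unique
# patterns with counts before any numerical work; for the two-arm, two-component
# trial design this leaves at most 8 patterns regardless of sample size.

log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

# Marginal negative log-likelihood and its gradient over par = c(beta, sigma).
# Per pattern the integrand mode is found by Newton steps (the integrand is
# log-concave in the random effect), the quadrature is recentred and rescaled
# there, and the gradient is the quadrature approximation of the exact
# score integral.
re_obj <- function(par, pat, z, w, grad = FALSE) {
  p <- ncol(pat$X1)
  beta <- par[seq_len(p)]
  sigma <- max(par[p + 1L], 1e-8)
  s2 <- sigma^2
  e1 <- drop(pat$X1 %*% beta)
  e2 <- drop(pat$X2 %*% beta)
  y1 <- pat$y1; y2 <- pat$y2; cnt <- pat$cnt
  q <- length(e1)

  b <- rep(0, q)
  for (it in 1:40) {
    p1 <- plogis(e1 + b); p2 <- plogis(e2 + b)
    g <- (y1 - p1) + (y2 - p2) - b / s2
    h <- p1 * (1 - p1) + p2 * (1 - p2) + 1 / s2
    step <- g / h
    b <- b + step
    if (max(abs(step)) < 1e-11) break
  }
  p1 <- plogis(e1 + b); p2 <- plogis(e2 + b)
  h <- p1 * (1 - p1) + p2 * (1 - p2) + 1 / s2
  s <- 1 / sqrt(h)

  nq <- length(z)
  B <- b + sqrt(2) * outer(s, z)                    # q x nq node locations
  E1 <- e1 + B; E2 <- e2 + B
  lp <- y1 * E1 - log1pexp(E1) + y2 * E2 - log1pexp(E2) -
    B^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
  lw <- sweep(lp, 2L, log(w) + z^2, "+")            # + log quadrature weights
  mx <- apply(lw, 1L, max)
  sumexp <- rowSums(exp(lw - mx))
  ll_pat <- log(sqrt(2) * s) + mx + log(sumexp)
  nll <- -sum(cnt * ll_pat)
  if (!grad) return(nll)

  W <- exp(lw - mx) / sumexp                        # normalized node weights
  P1 <- plogis(E1); P2 <- plogis(E2)
  A1 <- rowSums(W * (y1 - P1))
  A2 <- rowSums(W * (y2 - P2))
  gbeta <- drop(crossprod(pat$X1, cnt * A1) + crossprod(pat$X2, cnt * A2))
  gsigma <- sum(cnt * rowSums(W * (B^2 / sigma^3 - 1 / sigma)))
  list(nll = nll, grad = -c(gbeta, gsigma))
}

collapse_clusters <- function(X, y) {
  N <- length(y)
  i1 <- seq(1L, N, by = 2L)
  i2 <- i1 + 1L
  X1 <- X[i1, , drop = FALSE]
  X2 <- X[i2, , drop = FALSE]
  key <- do.call(paste, c(as.data.frame(cbind(X1, X2, y[i1], y[i2])), sep = "\r"))
  idx <- match(key, unique(key))
  first <- match(seq_len(max(idx)), idx)
  list(X1 = X1[first, , drop = FALSE], X2 = X2[first, , drop = FALSE],
       y1 = y[i1][first], y2 = y[i2][first],
       cnt = as.numeric(tabulate(idx)))
}

re_core <- function(X, y, n_quadrature = 15, init = NULL) {
  gh <- pracma::gaussHermite(n_quadrature)
  pat <- collapse_clusters(X, y)
  p <- ncol(X)

  if (is.null(init)) init <- logistic_core(X, y)
  start <- c(if (init$converged) init$beta else rep(0, p), 0.7)

  fn <- function(par) re_obj(par, pat, gh$x, gh$w, grad = FALSE)
  gr <- function(par) re_obj(par, pat, gh$x, gh$w, grad = TRUE)$grad
  opt <- optim(start, fn, gr, method = "L-BFGS-B",
               lower = c(rep(-Inf, p), 0), upper = c(rep(Inf, p), 25),
               control = list(maxit = 1000, factr = 10, pgtol = 1e-10))
  beta <- setNames(opt$par[seq_len(p)], colnames(X))
  sigma <- opt$par[p + 1L]
  converged <- opt$convergence == 0 && all(is.finite(beta))
  reason <- if (converged) NULL else paste("optimizer:", opt$message)

  boundary <- sigma < 1e-3
  vc <- matrix(NA_real_, p, p)
  if (converged) {
    hess <- tryCatch(optimHess(opt$par, fn, gr), error = function(e) NULL)
    full <- NULL
    if (!is.null(hess) && !boundary)
      full <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(full) && all(diag(full)[seq_len(p)] > 0)) {
      vc <- full[seq_len(p), seq_len(p), drop = FALSE]
    } else if (!is.null(hess)) {
      # variance component at (or near) its boundary, or indefinite joint
      # information: profile out sigma and use the beta block
      vcb <- tryCatch(solve(hess[seq_len(p), seq_len(p)]), error = function(e) NULL)
      if (!is.null(vcb) && all(diag(vcb) > 0)) {
        vc <- vcb
        if (!boundary) {
          converged <- FALSE
          reason <- "indefinite observed information for (beta, sigma)"
        }
      } else {
        converged <- FALSE
        reason <- "observed information is not invertible"
      }
    } else {
      converged <- FALSE
      reason <- "could not evaluate the observed information"
    }
    dimnames(vc) <- list(colnames(X), colnames(X))
  }
  list(beta = beta, vcov = vc, converged = converged,
       n_iter = opt$counts[["function"]], sigma2 = sigma^2,
       loglik = -opt$value, boundary = boundary, reason = reason)
}

#' Random-intercept logistic regression
#'
#' Fits `logit P(event | b_i) = b0 + b1 treatment + b2 component +
#' b3 treatment x component + g_i` with a participant-level random intercept
#' `g_i ~ Normal(0, sigma^2)`, maximizing the marginal likelihood. The
#' per-participant integral over the random effect is evaluated by adaptive
#' Gauss-Hermite quadrature (mode-and-curvature recentring per cluster
#' pattern). The coefficient covariance is the inverse observed information of
#' the marginal likelihood; `sigma^2` is bounded below at 0 and, when it lands
#' on that boundary, the covariance of the fixed effects is computed with
#' `sigma` profiled out.
#'
#' @inheritParams fit_logistic
#' @param n_quadrature Number of Gauss-Hermite nodes (default 15).
#' @return A `comphet_fit` with `extras$sigma2` (random-intercept variance),
#'   `extras$loglik`, and `extras$boundary`.
#' @examples
#' trial <- simulate_trial(scenario_spec(n = 400), seed = 1)
#' glance(fit_re_logistic(trial))
#' @export
fit_re_logistic <- function(data, n_quadrature = 15) {
  m <- trial_matrices(data)
  core <- re_core(m$X, m$y, n_quadrature = n_quadrature)
  new_comphet_fit("random_effects", core$beta, core$vcov, core$converged,
                  core$n_iter,
                  extras = list(sigma2 = core$sigma2, loglik = core$loglik,
                                boundary = core$boundary,
                                n_quadrature = n_quadrature),
                  nobs = length(m$y), n_participants = m$n_participants,
                  reason = core$reason)
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Evaluates the adaptive Gauss-Hermite approximation of the marginal
#' log-likelihood at given parameter values; mainly useful for checking the
#' quadrature against direct numerical integration.
#'
#' @inheritParams fit_re_logistic
#' @param beta Coefficient vector (intercept, treatment, component,
#'   interaction).
#' @param sigma Random-intercept standard deviation.
#' @return The marginal log-likelihood, a single number.
#' @export
re_loglik <- function(data, beta, sigma, n_quadrature = 15) {
  m <- trial_matrices(data)
  gh <- pracma::gaussHermite(n_quadrature)
  pat <- collapse_clusters(m$X, m$y)
  -re_obj(c(beta, sigma), pat, gh$x, gh$w, grad = FALSE)
}
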