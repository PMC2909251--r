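---
title: "Testing heterogeneity across the components of a binary composite outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing heterogeneity across the components of a binary composite outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Two-arm trials frequently use a binary composite primary outcome: the
endpoint has occurred if any one of a set of component events (say,
myocardial infarction or stroke) has occurred. A composite is only
interpretable as a single endpoint if the treatment acts similarly on its
components. `comphet` implements a direct test of that assumption for a
two-component composite: each participant contributes one binary outcome per
component, and the treatment-by-component interaction in a regression on the
component-level records quantifies *composite heterogeneity* — the degree to
which the two component odds ratios differ.

The component outcomes of one participant are correlated (intracluster
correlation `rho`), so the package fits four standard models for correlated
binary data and Wald-tests the interaction coefficient in each:

1. **Independent logistic regression** — `logit P(y) = b0 + b1 x1 + b2 x2 +
   b3 x1 x2` with `x1` the arm, `x2` the component, ignoring the pairing;
2. **Weighted logistic regression** — the same likelihood with
   Donald–Donner weights `1 / (1 + (m - 1) rho_hat)` from the ANOVA ICC
   estimator (`fit_weighted_dd()`), or Rao–Scott weights `1 / vif_j` from a
   per-arm design effect (`fit_weighted_rs()`);
3. **Population-average logistic regression (GEE)** — generalized estimating
   equations over participant clusters of size two with an unstructured
   working correlation and a robust sandwich covariance (`fit_gee()`);
4. **Random-intercept logistic regression** — a participant-level Gaussian
   random effect integrated out by adaptive Gauss–Hermite quadrature
   (`fit_re_logistic()`).

The heterogeneity test in every case is the two-sided Wald test of `b3`
(`wald_test(fit, "interaction")`). A Monte-Carlo driver
(`run_scenario()` / `run_power_study()`) estimates the power and type-I
error of these tests over pre-specified scenario grids.

## The simulated trial design

The scenario generator encodes the study conditions of the shipped power
tables; its defaults are those conditions, not tuning knobs:

* total sample size `n = 2000`, 1:1 allocation;
* control-arm composite event rate `R = 0.50`;
* within-participant correlation between the two components `rho = 0.10`
  (a value representative of major cardiovascular endpoints);
* component-1 odds ratio `or1 = 0.65` held fixed while `or2` sweeps
  0.65–1.20 to vary heterogeneity;
* balance ratio `ratio = p1 / p2` of the control component marginals, from
  1:5 to 5:1;
* two-sided `alpha = 0.05`.

The design mathematics are deterministic. Given `(R, ratio, rho)` the
control component marginals solve

```
p1 + p2 - [p1 p2 + rho * sqrt(p1 q1 p2 q2)] = R,   p1 = ratio * p2,
```

found by Brent root-finding on `p2` (`solve_component_probs()`, absolute
accuracy well below 1e-10; the round-trip to `R` is tested at 1e-9). The
treatment arm applies `or1`, `or2` to the control marginal odds and keeps
the same `rho`. The joint probability must respect the Fréchet bounds
`max(0, p1 + p2 - 1) <= p11 <= min(p1, p2)`; an unattainable `rho` raises an
error naming the violated bound rather than silently clamping.

### Correlated binary pairs from shared Poisson components

`simulate_pairs()` draws three independent Poisson counts
`X1, X2, X12` and sets `Z1 = X1 + X12`, `Z2 = X2 + X12`; the binary events
are the zero-count indicators `Yk = 1(Zk = 0)`. With total rates
`-log(pk)` and shared rate `alpha12 = log(1 + rho sqrt(p1 q1 p2 q2) /
(p1 p2))` this reproduces the target marginals, joint probability and
Pearson correlation exactly. Two consequences of this construction:

* only `rho >= 0` is representable (a shared component can only push the
  pair upward together), which covers the positive correlations seen among
  composite components;
* mapping the *event* to the zero count is a free choice — either coding
  reproduces the same first and second moments, and the package's moment
  tests validate the choice empirically rather than by authority.

Poisson counts are produced by inversion (`qpois` of uniforms), so two runs
with the same master seed share their underlying uniforms and the generated
data are monotonically coupled across scenarios. `run_power_study()`
exploits this: a grid run under one master seed is a common-random-numbers
experiment, which is how the monotonicity-of-power property is tested.

What the generator does *not* emulate: more than two components, covariates
beyond arm and component, differential follow-up or censoring, negative
within-participant correlation, and arm-specific correlation. Passing
Monte-Carlo tests therefore demonstrate correctness of the methods under
exchangeable two-component conditions, not robustness on arbitrary real
trial data.

## Model-fitting choices

**Logistic likelihoods.** `fit_logistic()` delegates the iteratively
reweighted least squares to `stats::glm.fit` with a tight deviance tolerance
(1e-12, 100 iterations) and reports the inverse Fisher information of the
(weighted) likelihood as covariance. Weights are frequency-type: a uniform
weight `w` leaves coefficients untouched and scales every standard error by
`1 / sqrt(w)` — that algebra is what makes the Donald–Donner fit's
conservatism transparent, and it is asserted in the tests. Fits with
coefficients walking past ±15 on the logit scale are flagged as
non-converged (separation) rather than reported.

**Weight estimators are deliberately untruncated.** The ANOVA ICC is
computed under a common-mean working model, so when the two components have
very different prevalences the prevalence gap inflates the within-pair mean
square and the estimate goes *negative* (about -0.10 at 1:5 balance even
though the true within-participant correlation is +0.10); likewise the
per-arm Rao–Scott design effect falls below 1 because cluster totals built
from unequal-p components are under-dispersed relative to a common-p
binomial. Truncating these estimators at 0 and 1 respectively would be
tempting, but the resulting weights above 1 are exactly how the weighted
fits correct for that under-dispersion — with truncation they collapse onto
the independent fit under imbalance and the characteristic behaviour of the
weighted procedures in the imbalanced scenarios (including the one cell
where ICC-weighting beats the GEE) disappears. The estimators are therefore
clamped only at their natural range limits (`[-1, 1]` for the ICC, a small
positive floor for the design effect).

**GEE.** Clusters have size two, so the working covariance inverse has a
closed 2×2 form and the estimating equations are solved by vectorized Fisher
scoring (coefficient-change tolerance 1e-8, 100 iterations). The single
unstructured working-correlation parameter is re-estimated each iteration
from Pearson residual cross-moments, scaled by the Pearson dispersion and
clamped to (-0.95, 0.95). The reported covariance is the robust sandwich
estimator without small-sample correction; with an independence working
structure the coefficients coincide *exactly* with the logistic fit (same
fixed point), which the tests assert, and the sandwich then equals the
clustered HC0 estimator, cross-checked against `sandwich::vcovCL`.

**Random intercepts.** The marginal likelihood integrates the participant
effect `g_i ~ N(0, sigma^2)` out of each cluster's contribution. Clusters
sharing a (covariate, outcome) pattern contribute identical terms, so the
likelihood is collapsed to unique patterns with counts — for this design at
most eight patterns, making the fit essentially independent of sample size.
Each pattern's integrand is log-concave; its mode is found by Newton steps
and a 15-node Gauss–Hermite rule is recentred and rescaled there (adaptive
quadrature). The optimizer is L-BFGS-B on `(beta, sigma)` with an analytic
gradient (the quadrature approximation of the exact score integral) and
`sigma >= 0`. The covariance is the inverse observed information from a
finite-difference Hessian of the gradient; when `sigma` lands on the zero
boundary the fixed-effect covariance is computed with `sigma` profiled out,
and an indefinite joint information away from the boundary marks the fit
non-converged. Fifteen nodes match the quadrature depth of standard
mixed-model software at this cluster size; the test suite checks the
quadrature against dense Simpson integration (1e-6) and the whole fit
against both a brute-force optimizer and `lme4::glmer`.

**Non-convergence policy.** In the Monte-Carlo driver a replicate on which
a model fails is excluded from that model's denominator only (and counted),
rather than being scored as a non-rejection: counting failures as
acceptances would bias power downward for exactly the models most prone to
failure. At the shipped scenario sizes failures are rare (< 1%).

## The two treatment-effect tests

Besides the heterogeneity test, the driver reports power for the treatment
effect, for which `composite_main_effect_test()` offers three routes:

* `"collapsed_score"` (default): collapse each participant to
  `max(y1, y2)` and compare arms by the two-proportion score test (Pearson
  chi-square without continuity correction). This is the test of "the
  treatment effect on the composite outcome" in the usual sense, and the
  treatment-effect columns of the shipped tables track its power: at
  `(or1, or2) = (0.65, 1.00)` its analytic normal approximation gives
  70.5%, matching the tabulated 70.7% within Monte-Carlo error, and the
  agreement holds across the rest of that grid.
* `"collapsed_chisq"`: the same comparison with the Yates continuity
  correction — the more conservative convention used to size the design.
* `"gee_no_interaction"`: stay at component level and Wald-test the
  treatment coefficient of a GEE with treatment and component terms only.
  This is a common-odds-ratio test that uses both component outcomes and is
  noticeably *more* powerful (about 76% in the same scenario); it answers a
  subtly different question and is therefore not the default.

## Analytic design power

`cc_chisq_power()` approximates the power of the continuity-corrected
chi-square test of equal proportions. The effect is reduced by the
correction `(1/n1 + 1/n2) / 2` and standardized by the *pooled* binomial
standard error `sqrt(pbar qbar (1/n1 + 1/n2))`, i.e. the normal
approximation built from the Pearson statistic's own noncentrality; both
rejection tails are accumulated. The pooled convention was chosen over the
unpooled-variance alternative because it reproduces the design statements
for this trial (88% against OR 0.75 and 97% against OR 0.70 at 1000 per
arm within half a percentage point, where the unpooled form overshoots
both). At equal proportions the formula returns the level, and it is
monotone in the sample size and in the effect size.

## Monte-Carlo scale and reproducibility

The shipped grids (`table1_grid()`, `table2_grid()`, `table3_grid()`) use
2000 replicates by default — a desk-scale choice under which a power near
90% carries a Monte-Carlo standard error of about 0.7 points; every result
row carries `mc_se`, so comparisons can be made at a principled tolerance,
and `n_reps = 10000` reproduces the original resolution when wanted. The
type-I-error checks use 5000 replicates. Per-replicate seeds are drawn once
from the master seed, so any single replicate can be regenerated in
isolation (`simulate_trial(spec, seed = rep_seed)`) and the driver's
results are exactly reproducible; a test asserts that the driver's
optimized inner loop and the public `simulate_trial() |> fit |> wald_test()`
route produce identical tallies.

## Known limitations

* Two components only in the shipped grids; the solver, generator and
  model code are written for the paired case (the regression machinery
  accepts the general layout, but no K > 2 generator is provided).
* No negative within-participant correlation (a limitation of the
  shared-component construction).
* Wald tests throughout; no likelihood-ratio or score variants for the
  heterogeneity test.
* The weighted-logistic covariances treat weights as frequency weights
  with no additional robustification — deliberately matching the classical
  weighted procedures, whose conservatism (null rejection rates near 3%)
  is part of the phenomenon under study.
* The analytic power formula is a normal approximation; no exact
  enumeration-based power is provided.
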