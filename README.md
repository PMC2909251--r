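# comphet

Heterogeneity tests for the components of a binary composite outcome in a
two-arm clinical trial.

## What problem this solves

Trials often use a binary composite primary outcome — the endpoint occurs if
any of several component events (e.g. myocardial infarction, stroke,
cardiovascular death) occurs. A significant composite result is hard to
interpret if the treatment effect differs across components. For a
two-component composite, `comphet` tests that *composite heterogeneity*
directly: each participant contributes one binary record per component, and
the component-level regression

    logit P(y_ik = 1) = b0 + b1 x1 + b2 x2 + b3 x1 x2

(`x1` arm, `x2` component) carries the heterogeneity in the
treatment-by-component interaction `b3 = log(OR2 / OR1)`. Because the two
outcomes of one participant are correlated (intracluster correlation `rho`),
the package fits this model four ways and Wald-tests `b3` in each:

| model | function | variance |
|---|---|---|
| independent logistic | `fit_logistic()` | inverse Fisher information |
| ICC-weighted logistic (Donald–Donner, Rao–Scott) | `fit_weighted_dd()`, `fit_weighted_rs()` | weighted information |
| population-average GEE, unstructured working correlation | `fit_gee()` | robust sandwich |
| random-intercept logistic, adaptive Gauss–Hermite | `fit_re_logistic()` | observed information |

It also ships the pieces a power investigation of these tests needs: exact
design mathematics (`solve_component_probs()`, `build_arm_designs()`,
`cc_chisq_power()`), a correlated binary simulator built from sums of shared
Poisson components (`simulate_trial()`), treatment-effect tests on the
composite (`composite_main_effect_test()`), and a Monte-Carlo driver with
pre-specified scenario grids (`run_scenario()`, `run_power_study()`,
`table1_grid()`–`table3_grid()`). Audience: trial statisticians designing or
reviewing composite endpoints, and anyone reproducing the power study the
defaults encode (n = 2000, control composite rate 0.50, `rho` = 0.10,
OR1 = 0.65, two-sided alpha 0.05).

## Worked example

```r
library(comphet)

spec <- scenario_spec(n = 2000, control_rate = 0.5, icc = 0.10,
                      or1 = 0.65, or2 = 1.00)   # moderate heterogeneity
design_report(spec)[, c("p1_control", "composite_treatment", "composite_or")]
#> # A tibble: 1 × 3
#>   p1_control composite_treatment composite_or
#>        <dbl>               <dbl>        <dbl>
#> 1      0.308               0.444        0.799

trial <- simulate_trial(spec, seed = 7)
fit <- fit_gee(trial)
wald_test(fit, "interaction")
#> # A tibble: 1 × 7
#>   term        estimate std.error statistic p.value alpha reject
#>   <chr>          <dbl>     <dbl>     <dbl>   <dbl> <dbl> <lgl>
#> 1 interaction    0.294     0.131      2.24  0.0252  0.05 TRUE
```

The control arm needs component marginals of 0.308 each for a 50% composite
rate at `rho` = 0.10; under OR2 = 1.00 the treatment composite rate is 0.444
(composite OR 0.80). On this simulated trial the GEE interaction estimate is
0.294 — the true value is `log(1.00/0.65) = 0.431` — and the heterogeneity
test rejects at the 5% level (p = 0.025).

Power for a whole scenario, all models at once:

```r
run_scenario(spec, models = c("independent", "weighted_dd", "gee"),
             n_reps = 2000, seed = 1)[, c("model", "power", "mc_se")]
#> # A tibble: 3 × 3
#>   model       power   mc_se
#>   <chr>       <dbl>   <dbl>
#> 1 independent 0.869 0.00754
#> 2 weighted_dd 0.848 0.00802
#> 3 gee         0.89  0.00700
```

GEE has the greatest power (89.0% here), plain logistic next, the
ICC-weighted fit least — with Monte-Carlo standard errors under a point.
`run_power_study(table1_grid(), ...)` sweeps OR2 over 0.65–1.20 the same
way, `render_power_table()` pivots the result into the publication layout,
and `plot_power_curves()` / `autoplot()` draw power against OR2.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "composite-het.R", package = "comphet"))')" \
  design --control-rate 0.5 --icc 0.1 --or1 0.65 --or2 1.0 --ratio 1:1 --n 2000
```

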