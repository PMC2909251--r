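all_model_tags <- c("independent", "weighted_dd", "weighted_rs", "gee",
                    "random_effects")

#' Monte-Carlo power / type-I error for one scenario
#'
#' Simulates `n_reps` trials under a scenario and, per replicate, fits each
#' requested model and applies the requested tests: `"interaction"` is the
#' composite-heterogeneity Wald test on the full model; `"treatment"` is the
#' main-effect Wald test on the model refitted without the interaction term;
#' `"composite"` is the model-free treatment test on the collapsed composite
#' indicator (two-proportion score test, see
#' [composite_main_effect_test()]), reported once per scenario with model tag
#' `"collapsed"`. Replicates in which a model fails to converge are counted
#' and excluded from that model's rejection-rate denominator only.
#'
#' Per-replicate seeds are drawn once from the master `seed`, so results are
#' exactly reproducible and two calls with the same `seed` and `n_reps` share
#' their random draws across scenarios (common random numbers).
#'
#' @param spec A scenario from [scenario_spec()].
#' @param models Character vector of model tags (subset of `"independent"`,
#'   `"weighted_dd"`, `"weighted_rs"`, `"gee"`, `"random_effects"`).
#' @param tests Character vector: `"interaction"`, `"treatment"`, or both.
#' @param n_reps Number of simulated trials.
#' @param seed Master seed for replicate-seed generation.
#' @param n_quadrature Gauss-Hermite nodes for the random-effects model.
#' @param progress Print a progress line every 100 replicates?
#' @return A tibble of class `comphet_power`, one row per model x test, with
#'   the scenario parameters, `n_reps`, `n_converged`, `n_reject`, `power`
#'   (= n_reject / n_converged), and the Monte-Carlo standard error `mc_se`.
#' @examples
#' run_scenario(scenario_spec(n = 200, or2 = 1.2), models = "gee",
#'              n_reps = 20, seed = 1)
#' @export
run_scenario <- function(spec, models = "gee", tests = "interaction",
                         n_reps = 2000, seed = 1L, n_quadrature = 15,
                         progress = FALSE) {
  validate_scenario(spec)
  models <- match.arg(models, all_model_tags, several.ok = TRUE)
  tests <- match.arg(tests, c("interaction", "treatment", "composite"),
                     several.ok = TRUE)
  if (n_reps < 1) abort("n_reps must be at least 1")
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)

  # fixed design: probabilities and covariates do not change across replicates
  arms <- build_arm_designs(spec)
  n_t <- as.integer(round(spec$n * spec$allocation / (1 + spec$allocation)))
  n_c <- as.integer(spec$n) - n_t
  x1 <- rep(c(0, 1), times = c(2L * n_c, 2L * n_t))
  x2 <- rep_len(c(0, 1), 2L * (n_c + n_t))
  X4 <- cbind("(Intercept)" = 1, treatment = x1, component = x2,
              "treatment:component" = x1 * x2)
  X3 <- X4[, 1:3, drop = FALSE]

  combos <- expand.grid(model = models, test = setdiff(tests, "composite"),
                        stringsAsFactors = FALSE)
  if ("composite" %in% tests)
    combos <- rbind(combos, data.frame(model = "collapsed", test = "composite"))
  if ("weighted_rs" %in% combos$model[combos$test == "treatment"])
    abort("the treatment (main-effect) test is not provided for weighted_rs")
  n_conv <- setNames(integer(nrow(combos)), paste(combos$model, combos$test))
  n_rej <- n_conv

  for (r in seq_len(n_reps)) {
    # identical RNG stream to simulate_trial(spec, seed = rep_seeds[r])
    set.seed(rep_seeds[r])
    yc <- sim_pairs_matrix(n_c, arms$p1[1], arms$p2[1], spec$icc)
    yt <- sim_pairs_matrix(n_t, arms$p1[2], arms$p2[2], spec$icc)
    y <- c(as.vector(t(yc)), as.vector(t(yt)))

    init <- list()  # logistic fit shared across models, per design
    get_init <- function(int) {
      key <- if (int) "i4" else "i3"
      if (is.null(init[[key]]))
        init[[key]] <<- logistic_core(if (int) X4 else X3, y)
      init[[key]]
    }
    for (i in seq_len(nrow(combos))) {
      if (combos$test[i] == "composite") {
        # two-proportion score test on the collapsed composite indicator
        pc <- mean(yc[, 1] | yc[, 2])
        pt <- mean(yt[, 1] | yt[, 2])
        pbar <- (n_c * pc + n_t * pt) / (n_c + n_t)
        if (pbar > 0 && pbar < 1) {
          chisq <- (pc - pt)^2 / (pbar * (1 - pbar) * (1 / n_c + 1 / n_t))
          n_conv[i] <- n_conv[i] + 1L
          n_rej[i] <- n_rej[i] +
            as.integer(chisq > qchisq(1 - spec$alpha, df = 1))
        }
        next
      }
      int <- combos$test[i] == "interaction"
      X <- if (int) X4 else X3
      term <- if (int) "treatment:component" else "treatment"
      core <- tryCatch(switch(combos$model[i],
        independent = get_init(int),
        weighted_dd = {
          rho <- icc_core(y)
          logistic_core(X, y, rep(1 / (1 + rho), length(y)))
        },
        weighted_rs = rs_core(X, y),
        gee = gee_core(X, y, init = get_init(int)),
        random_effects = re_core(X, y, n_quadrature = n_quadrature,
                                 init = get_init(int))
      ), error = function(e) NULL)
      if (!is.null(core) && isTRUE(core$converged)) {
        se <- sqrt(core$vcov[term, term])
        p <- 2 * pnorm(-abs(core$beta[[term]] / se))
        n_conv[i] <- n_conv[i] + 1L
        n_rej[i] <- n_rej[i] + as.integer(p < spec$alpha)
      }
    }
    if (progress && r %% 100 == 0)
      message(sprintf("replicate %d/%d: rejections %s", r, n_reps,
                      paste(names(n_rej), n_rej, sep = "=", collapse = " ")))
  }

  power <- ifelse(n_conv > 0, n_rej / n_conv, NA_real_)
  out <- tibble(
    n = spec$n, control_rate = spec$control_rate, icc = spec$icc,
    or1 = spec$or1, or2 = spec$or2, ratio = spec$ratio, alpha = spec$alpha,
    model = combos$model, test = combos$test,
    n_reps = as.integer(n_reps), n_converged = unname(n_conv),
    n_reject = unname(n_rej), power = unname(power),
    mc_se = unname(sqrt(power * (1 - power) / pmax(n_conv, 1)))
  )
  class(out) <- c("comphet_power", class(out))
  out
}

#' Run a power study over a grid of scenarios
#'
#' Applies [run_scenario()] to each row of a scenario grid (for example
#' [table1_grid()]). All scenarios share the same master seed and therefore
#' the same per-replicate seeds, giving common random numbers across the
#' grid.
#'
#' @param scenarios A tibble of scenarios, one per row, with the columns of
#'   [scenario_spec()].
#' @inheritParams run_scenario
#' @return A `comphet_power` tibble with one row per scenario x model x test.
#' @export
run_power_study <- function(scenarios, models = "gee", tests = "interaction",
                            n_reps = 2000, seed = 1L, n_quadrature = 15,
                            progress = FALSE) {
  out <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    run_scenario(scenarios[i, , drop = FALSE], models = models, tests = tests,
                 n_reps = n_reps, seed = seed, n_quadrature = n_quadrature,
                 progress = progress)
  }) %>% dplyr::bind_rows()
  class(out) <- c("comphet_power", class(out))
  out
}

#' Scenario grids for the shipped power tables
#'
#' Three pre-specified grids, all with n = 2000, control composite rate 0.50,
#' within-participant correlation 0.10, and two-sided alpha 0.05:
#' * `table1_grid()`: balanced components, OR1 = 0.65, OR2 from 0.65 to 1.20
#'   in steps of 0.05 (increasing heterogeneity);
#' * `table2_grid()`: fixed (OR1, OR2) = (0.65, 1.00) with balance ratios
#'   1:1, 1:3, 1:5, 3:1, 5:1 (p1:p2);
#' * `table3_grid()`: OR1 in \{0.65, 0.70, 0.75\} crossed with OR2 from OR1
#'   to 1.20, balanced components.
#'
#' @return A tibble of scenarios, one per row.
#' @examples
#' nrow(table1_grid())  # 12
#' @export
table1_grid <- function() {
  or2 <- seq(0.65, 1.20, by = 0.05)
  dplyr::bind_rows(lapply(or2, function(o2) scenario_spec(or1 = 0.65, or2 = o2)))
}

#' @rdname table1_grid
#' @export
table2_grid <- function() {
  ratios <- c(1, 1 / 3, 1 / 5, 3, 5)
  dplyr::bind_rows(lapply(ratios, function(r)
    scenario_spec(or1 = 0.65, or2 = 1.00, ratio = r)))
}

#' @rdname table1_grid
#' @export
table3_grid <- function() {
  grid <- expand.grid(or1 = c(0.65, 0.70, 0.75),
                      or2 = seq(0.65, 1.20, by = 0.05))
  grid <- grid[grid$or2 >= grid$or1 - 1e-9, ]
  grid <- grid[order(grid$or1, grid$or2), ]
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i)
    scenario_spec(or1 = grid$or1[i], or2 = grid$or2[i])))
}

#' Lay out power-study results as a publication-style table
#'
#' Pivots a `comphet_power` result into the row/column structure of the
#' shipped tables: layout 1 and 3 put OR2 on rows, layout 2 puts the balance
#' ratio on rows; model columns hold power in percent (one decimal) and each
#' has a companion Monte-Carlo standard error column. Missing cells are
#' rendered as `NA` with a warning.
#'
#' @param results A `comphet_power` tibble.
#' @param layout 1, 2 or 3.
#' @return A wide tibble.
#' @export
render_power_table <- function(results, layout = 1) {
  if (!layout %in% 1:3) abort("layout must be 1, 2 or 3")
  if (layout == 3 && length(unique(results$model)) > 1)
    abort("layout 3 (treatment vs heterogeneity power) expects results from a single model")
  res <- as_tibble(results) %>%
    dplyr::mutate(power_pct = round(100 * .data$power, 1),
                  mc_se_pct = round(100 * .data$mc_se, 2))
  rows <- switch(as.character(layout),
                 "1" = "or2", "2" = "ratio", "3" = c("or1", "or2"))
  cols <- if (layout == 3) "test" else "model"
  wide <- res %>%
    dplyr::select(dplyr::all_of(c(rows, cols)), "power_pct", "mc_se_pct") %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(cols),
                       values_from = c("power_pct", "mc_se_pct"))
  if (anyNA(wide))
    warn("some table cells are missing from the supplied results")
  dplyr::arrange(wide, dplyr::across(dplyr::all_of(rows)))
}

#' Plot power curves against the second component's odds ratio
#'
#' @param results A `comphet_power` tibble containing interaction-test rows
#'   over a range of `or2`.
#' @return A ggplot object: power (percent) against OR2, one line per model.
#' @export
plot_power_curves <- function(results) {
  res <- dplyr::filter(as_tibble(results), .data$test == "interaction")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$or2, y = 100 * .data$power,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "odds ratio of component 2 (OR2)", y = "power (%)",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comphet_power <- function(object, ...) plot_power_curves(object)
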