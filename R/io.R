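#' Read long-format trial data from CSV
#'
#' Expects the schema written by [write_trial_csv()]: a header
#' `participant_id,arm,component,event` with integer 0/1 codes for arm,
#' component and event, and exactly one row per (participant, component).
#' Violations raise errors naming the offending row or participant.
#'
#' @param path Path to a CSV file.
#' @return A validated trial-data tibble.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  dat <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_integer(),
    arm = readr::col_integer(),
    component = readr::col_integer(),
    event = readr::col_integer()
  ), progress = FALSE)
  prob <- readr::problems(dat)
  if (nrow(prob) > 0)
    abort(sprintf("could not parse %s: row %d, column %s", path,
                  prob$row[1], prob$col[1]))
  check_trial_data(dat)
  dat
}

#' Write long-format trial data to CSV
#'
#' Comma-separated, LF line endings, no row-index column.
#'
#' @param data A trial-data tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  check_trial_data(data)
  readr::write_csv(data[, c("participant_id", "arm", "component", "event")],
                   path, eol = "\n", progress = FALSE)
  invisible(path)
}

config_defaults <- list(
  n = 2000L, allocation = 1, control_rate = 0.5, icc = 0.10,
  or1 = 0.65, or2 = 0.65, ratio = 1, alpha = 0.05,
  reps = 2000L, seed = 1L, quadrature = 15L,
  models = "gee", tests = "interaction"
)

#' Load a run configuration from YAML or JSON
#'
#' Reads a flat key-value configuration, fills in defaults (2000 replicates,
#' alpha 0.05, 15 quadrature nodes, ...), parses `ratio` strings like
#' `"1:5"`, and validates everything against the scenario rules. Unknown keys
#' are rejected.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A list with a validated `scenario` tibble plus execution options
#'   `reps`, `seed`, `quadrature`, `models`, `tests`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(config_defaults))
  if (length(unknown) > 0)
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(config_defaults, raw)
  if (is.character(cfg$ratio)) cfg$ratio <- parse_ratio(cfg$ratio)
  scenario <- scenario_spec(
    n = cfg$n, allocation = cfg$allocation, control_rate = cfg$control_rate,
    icc = cfg$icc, or1 = cfg$or1, or2 = cfg$or2, ratio = cfg$ratio,
    alpha = cfg$alpha
  )
  if (cfg$reps < 1) abort("reps must be at least 1")
  if (cfg$quadrature < 2) abort("quadrature must be at least 2")
  bad <- setdiff(cfg$models, all_model_tags)
  if (length(bad) > 0)
    abort(paste0("unknown models: ", paste(bad, collapse = ", ")))
  bad_t <- setdiff(cfg$tests, c("interaction", "treatment"))
  if (length(bad_t) > 0)
    abort(paste0("unknown tests: ", paste(bad_t, collapse = ", ")))
  list(scenario = scenario, reps = as.integer(cfg$reps),
       seed = as.integer(cfg$seed), quadrature = as.integer(cfg$quadrature),
       models = cfg$models, tests = cfg$tests)
}
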