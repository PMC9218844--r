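#' Default run configuration
#'
#' All knobs of a model run with their defaults: the base-case societal
#' perspective, the main population, 10,000 patients, explicit seed, the
#' packaged life table, PSA settings (1000 x 10,000 at full scale), no
#' scenario flags, and no parameter overrides.
#'
#' @return a named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    population = "main",
    perspective = "societal",
    n_patients = 10000L,
    seed = 1L,
    wtp = 50000,
    session_mode = "observed",
    n_sessions_fixed = 16,
    pr_session_cost_override = NULL,
    life_table = NULL,            # NULL = packaged synthetic table
    calibrate_le_target = NULL,   # e.g. 8.85 to calibrate before running
    psa = list(n_outer = 1000L, n_inner = 10000L, scope = "standard",
               n_eff = 2704),
    scenario = list(drop_utility_effect = FALSE, drop_mortality_effect = FALSE,
                    readmission_hr_override = NULL),
    overrides = list(),
    output_dir = "."
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Missing keys take their defaults; unknown top-level keys and unknown
#' parameter-override names are rejected by name. `path = NULL` or an empty
#' file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param registry registry used to validate `overrides` keys.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL, registry = default_registry()) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    if (nm %in% c("psa", "scenario")) {
      bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("unknown ", nm, " key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else cfg[[nm]] <- user[[nm]]
  }
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("seed must be a single explicit integer", call. = FALSE)
  if (!cfg$population %in% c("main", "younger"))
    stop("population must be 'main' or 'younger'", call. = FALSE)
  if (!cfg$perspective %in% c("societal", "health_system"))
    stop("perspective must be 'societal' or 'health_system'", call. = FALSE)
  if (!is.null(cfg$life_table) && !file.exists(cfg$life_table))
    stop("life table not found: ", cfg$life_table, call. = FALSE)
  # validates override names against the registry
  apply_config_overrides(registry, cfg$overrides)
  cfg
}

#' Run the base-case model from a configuration
#'
#' Resolves the configuration (registry overrides, life table, optional
#' excess-mortality calibration) and runs the PR vs no-PR comparison.
#'
#' @param config a [load_config()] / [default_config()] object.
#' @param registry parameter registry before overrides.
#' @return a `pr_comparison`.
#' @export
run_from_config <- function(config = default_config(),
                            registry = default_registry()) {
  registry <- apply_config_overrides(registry, config$overrides)
  draw <- base_draw(registry)
  lt <- if (is.null(config$life_table)) read_life_table()
        else read_life_table(config$life_table)
  model <- mortality_model(life_table = lt, draw = draw)
  if (!is.null(config$calibrate_le_target))
    model <- calibrate_excess_mortality(config$calibrate_le_target, model,
                                        draw, seed = config$seed)
  pr_strategy <- strategy_spec(
    "PR", session_mode = config$session_mode,
    n_sessions_fixed = config$n_sessions_fixed,
    apply_utility_increment = !isTRUE(config$scenario$drop_utility_effect),
    apply_mortality_hr = !isTRUE(config$scenario$drop_mortality_effect),
    readmission_hr_override = config$scenario$readmission_hr_override)
  run_comparison(config$n_patients, draw, model,
                 population = config$population,
                 perspective = config$perspective,
                 seed = config$seed, wtp = config$wtp,
                 pr_strategy = pr_strategy,
                 pr_session_cost_override = config$pr_session_cost_override)
}

comparison_table <- function(comparison) {
  stopifnot(inherits(comparison, "pr_comparison"))
  no <- comparison$nopr$stats
  pr <- comparison$pr$stats
  stopifnot(identical(no$metric, pr$metric))
  data.frame(metric = no$metric,
             no_PR = no$mean, no_PR_lo = no$lo, no_PR_hi = no$hi,
             PR = pr$mean, PR_lo = pr$lo, PR_hi = pr$hi,
             difference = pr$mean - no$mean)
}

# full-precision numeric formatting so CSV round-trips bit-for-bit
fmt17 <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write comparison results to CSV or JSON
#'
#' The strategy table has one row per reported outcome (lifetime cost, QALYs,
#' life expectancy, year-1 rates and category costs, post-year-1 costs) and
#' columns for the no-PR mean and interval, the PR mean and interval, and the
#' PR minus no-PR difference. Numbers are written at full precision so a
#' written table re-parses to identical doubles.
#'
#' @param comparison a `pr_comparison` from [run_comparison()] /
#'   [run_from_config()].
#' @param format `"csv"` or `"json"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(comparison, format = c("csv", "json"), path) {
  format <- match.arg(format)
  tab <- comparison_table(comparison)
  if (format == "csv") {
    out <- tab
    for (cl in setdiff(names(out), "metric")) out[[cl]] <- fmt17(out[[cl]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "columns", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return the strategy table as a data frame with numeric columns.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- utils::read.csv(path, colClasses = c(metric = "character"))
    for (cl in setdiff(names(tab), "metric")) tab[[cl]] <- as.numeric(tab[[cl]])
    tab
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Write PSA artifacts to CSV
#'
#' Per-draw table (draw id, sampled parameter values, incremental cost and
#' QALYs, dominance flag) and the CEAC grid.
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param draws_path,ceac_path output CSV paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
write_psa <- function(psa, draws_path = NULL, ceac_path = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (!is.null(draws_path))
    utils::write.csv(psa$draws, draws_path, row.names = FALSE, quote = FALSE)
  if (!is.null(ceac_path))
    utils::write.csv(psa$ceac, ceac_path, row.names = FALSE, quote = FALSE)
  invisible(c(draws = draws_path, ceac = ceac_path))
}
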