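#' Two-level probabilistic sensitivity analysis
#'
#' Outer loop: `n_outer` parameter draws from the uncertainty distributions in
#' `psa_scope` ([sample_parameter_draw()]). Inner loop: for each draw, both
#' strategies are run on a common `n_inner`-patient cohort with common random
#' numbers across strategies; the same inner substream is reused across outer
#' draws so that between-draw variation isolates parameter uncertainty (with
#' an empty scope the between-draw variance is exactly zero). Prediction
#' intervals are the 2.5th/97.5th percentiles of the per-draw incremental
#' cohort means. The cost-effectiveness acceptability curve (CEAC) gives, on
#' the willingness-to-pay grid, the proportion of draws where PR has positive
#' net monetary benefit.
#'
#' @param n_outer number of outer parameter draws (>= 1).
#' @param n_inner inner microsimulation cohort size (>= 1).
#' @param registry parameter registry.
#' @param psa_scope names sampled in the outer loop ([default_psa_scope()]).
#' @param wtp_grid willingness-to-pay grid for the CEAC, USD/QALY.
#' @param seed master seed.
#' @param model mortality model (calibrate before the PSA if desired).
#' @param population,perspective passed to [run_comparison()].
#' @param n_eff effective n for `psa = "mean"` entries.
#' @return an object of class `psa_result`: `$draws` (per-draw data frame
#'   with sampled scope values, `delta_cost`, `delta_qaly`, `dominant`),
#'   `$pi_delta_cost`, `$pi_delta_qaly`, `$prob_pr_dominant`, `$ceac`.
#' @export
run_psa <- function(n_outer, n_inner, registry = default_registry(),
                    psa_scope = default_psa_scope(registry),
                    wtp_grid = seq(0, 200000, by = 25000),
                    seed = 1L, model = NULL, population = "main",
                    perspective = "societal", n_eff = 2704) {
  stopifnot(n_outer >= 1, n_inner >= 1)
  if (!length(wtp_grid)) stop("wtp_grid must be nonempty", call. = FALSE)
  if (is.null(model)) model <- mortality_model(draw = base_draw(registry))
  inner_seed <- substream_seed(seed, "inner")
  rows <- vector("list", n_outer)
  for (i in seq_len(n_outer)) {
    draw <- with_seed(substream_seed(seed, "psa-draw", i),
                      sample_parameter_draw(registry, psa_scope, n_eff))
    cmp <- run_comparison(n_inner, draw, model, population, perspective,
                          seed = inner_seed)
    scope_vals <- lapply(draw$sampled, function(nm) {
      v <- draw_value(draw, nm)
      if (length(v) > 1) NULL else v
    })
    names(scope_vals) <- draw$sampled
    scope_vals <- scope_vals[!vapply(scope_vals, is.null, logical(1))]
    row <- data.frame(
      draw = i,
      delta_cost = cmp$incremental$delta_cost,
      delta_qaly = cmp$incremental$delta_qaly,
      delta_le = cmp$incremental$delta_le,
      dominant = cmp$incremental$dominance == "PR dominant")
    if (length(scope_vals))
      row <- cbind(row, as.data.frame(scope_vals, check.names = FALSE))
    rows[[i]] <- row
  }
  draws <- do.call(rbind, rows)
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_pr_optimal = vapply(wtp_grid, function(w)
      mean(w * draws$delta_qaly - draws$delta_cost > 0), numeric(1)))
  structure(list(
    draws = draws,
    pi_delta_cost = interval_cont(draws$delta_cost),
    pi_delta_qaly = interval_cont(draws$delta_qaly),
    prob_pr_dominant = mean(draws$dominant),
    ceac = ceac,
    n_outer = n_outer, n_inner = n_inner), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d draws x %d patients>\n", x$n_outer, x$n_inner))
  cat(sprintf("  P(PR dominant) = %.3f\n", x$prob_pr_dominant))
  cat(sprintf("  delta cost 95%% PI: [%.0f, %.0f]\n",
              x$pi_delta_cost[1], x$pi_delta_cost[2]))
  cat(sprintf("  delta QALY 95%% PI: [%.3f, %.3f]\n",
              x$pi_delta_qaly[1], x$pi_delta_qaly[2]))
  invisible(x)
}

# Build (registry, config tweaks) for a one-way sensitivity value. Special
# names: "pr_sessions_fixed" switches the PR arm to fixed-session mode;
# "pr_session_cost" overrides the all-in per-session cost.
owsa_settings <- function(registry, param_name, value) {
  pr_strategy <- strategy_spec("PR")
  session_cost <- NULL
  if (param_name == "pr_sessions_fixed") {
    pr_strategy <- strategy_spec("PR", session_mode = "fixed",
                                 n_sessions_fixed = value)
  } else if (param_name == "pr_session_cost") {
    session_cost <- value
  } else {
    registry <- set_param_value(registry, param_name, value)
  }
  list(registry = registry, pr_strategy = pr_strategy,
       session_cost = session_cost)
}

#' One-way sensitivity analysis
#'
#' Runs the base-case comparison with one parameter pinned to its low and
#' high bound (all else at base case, same seed), returning both incremental
#' results for tornado-style reporting. Besides registry parameter names, two
#' analysis knobs are recognised: `"pr_sessions_fixed"` (all PR patients take
#' exactly that many sessions) and `"pr_session_cost"` (all-in USD per
#' session).
#'
#' @param param_name parameter to vary.
#' @param low,high bounds (low <= high).
#' @param n_inner cohort size.
#' @param seed integer seed.
#' @param registry parameter registry.
#' @param model mortality model.
#' @param ... passed to [run_comparison()].
#' @return list with `param`, `values`, and `$low`, `$high` `pr_comparison`
#'   objects.
#' @export
one_way_sensitivity <- function(param_name, low, high, n_inner = 10000,
                                seed = 1L, registry = default_registry(),
                                model = NULL, ...) {
  if (low > high) stop("require low <= high", call. = FALSE)
  extra <- !param_name %in% c("pr_sessions_fixed", "pr_session_cost")
  if (extra) get_param(registry, param_name)  # validates the name
  run_at <- function(v) {
    st <- owsa_settings(registry, param_name, v)
    draw <- base_draw(st$registry)
    m <- if (is.null(model)) mortality_model(draw = draw) else model
    run_comparison(n_inner, draw, m, seed = seed,
                   pr_strategy = st$pr_strategy,
                   pr_session_cost_override = st$session_cost, ...)
  }
  list(param = param_name, values = c(low = low, high = high),
       low = run_at(low), high = run_at(high))
}

#' Scenario flags
#'
#' @param drop_utility_effect drop the PR utility increment.
#' @param drop_mortality_effect drop the PR mortality hazard ratio.
#' @param readmission_hr_override optional positive readmission HR override
#'   (1 = no readmission effect).
#' @return a list of class `scenario_flags`.
#' @export
scenario_flags <- function(drop_utility_effect = FALSE,
                           drop_mortality_effect = FALSE,
                           readmission_hr_override = NULL) {
  if (!is.null(readmission_hr_override))
    assert_scalar_num(readmission_hr_override, "readmission_hr_override",
                      lower = 1e-12)
  structure(list(drop_utility_effect = isTRUE(drop_utility_effect),
                 drop_mortality_effect = isTRUE(drop_mortality_effect),
                 readmission_hr_override = readmission_hr_override),
            class = "scenario_flags")
}

#' Scenario analysis
#'
#' Applies scenario flags to the PR strategy (no quality-of-life effect, no
#' mortality effect, readmission hazard ratio forced to a given value) and
#' runs the base-case comparison.
#'
#' @param flags a [scenario_flags()] object.
#' @param n_inner cohort size.
#' @param seed integer seed.
#' @param registry parameter registry.
#' @param model mortality model.
#' @param ... passed to [run_comparison()].
#' @return a `pr_comparison`.
#' @export
scenario_analysis <- function(flags, n_inner = 10000, seed = 1L,
                              registry = default_registry(), model = NULL,
                              ...) {
  stopifnot(inherits(flags, "scenario_flags"))
  draw <- base_draw(registry)
  if (is.null(model)) model <- mortality_model(draw = draw)
  pr_strategy <- strategy_spec(
    "PR",
    apply_utility_increment = !flags$drop_utility_effect,
    apply_mortality_hr = !flags$drop_mortality_effect,
    readmission_hr_override = flags$readmission_hr_override)
  run_comparison(n_inner, draw, model, seed = seed, pr_strategy = pr_strategy,
                 ...)
}

#' Threshold cost per PR session
#'
#' Bisection (tolerance $1) on the all-in cost per PR session, with every PR
#' patient taking exactly `n_sessions` sessions, for the cost at which PR
#' stops being cost saving (`"cost_saving"`: incremental cost = 0) or at
#' which the ICER reaches $50,000 or $100,000 per QALY (`"icer_50k"`,
#' `"icer_100k"`; root of incremental cost - wtp x incremental QALY). The
#' comparison is re-run at each candidate cost with the same seed, so the
#' objective is deterministic and monotone in the session cost.
#'
#' @param criterion `"cost_saving"`, `"icer_50k"` or `"icer_100k"`.
#' @param n_sessions fixed session count (default 36, a full program).
#' @param n_inner cohort size.
#' @param seed integer seed.
#' @param registry parameter registry.
#' @param model mortality model.
#' @param bracket search interval in USD per session.
#' @param tol bisection tolerance, USD.
#' @param flags optional [scenario_flags()] applied to the PR arm.
#' @param ... passed to [run_comparison()].
#' @return threshold USD per session.
#' @export
threshold_cost_per_session <- function(criterion = c("cost_saving", "icer_50k",
                                                     "icer_100k"),
                                       n_sessions = 36, n_inner = 2000,
                                       seed = 1L,
                                       registry = default_registry(),
                                       model = NULL,
                                       bracket = c(0, 10000), tol = 1,
                                       flags = scenario_flags(), ...) {
  criterion <- match.arg(criterion)
  stopifnot(n_sessions >= 1)
  wtp <- switch(criterion, cost_saving = 0, icer_50k = 50000,
                icer_100k = 100000)
  draw <- base_draw(registry)
  if (is.null(model)) model <- mortality_model(draw = draw)
  pr_strategy <- strategy_spec(
    "PR", session_mode = "fixed", n_sessions_fixed = n_sessions,
    apply_utility_increment = !flags$drop_utility_effect,
    apply_mortality_hr = !flags$drop_mortality_effect,
    readmission_hr_override = flags$readmission_hr_override)
  f <- function(cost) {
    cmp <- run_comparison(n_inner, draw, model, seed = seed,
                          pr_strategy = pr_strategy,
                          pr_session_cost_override = cost, ...)
    cmp$incremental$delta_cost - wtp * cmp$incremental$delta_qaly
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("criterion '%s' not bracketed within [$%g, $%g] per session",
                 criterion, lo, hi), call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
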