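#' Discount a cost or QALY accrual
#'
#' End-of-convention used throughout the model: year 1 is undiscounted and
#' year `k` is divided by `(1 + rate)^(k - 1)`.
#'
#' @param amount USD or QALY amount.
#' @param cycle_index 1-based model year.
#' @param rate annual discount rate (>= 0).
#' @return discounted amount.
#' @export
discount <- function(amount, cycle_index, rate = 0.03) {
  if (any(cycle_index < 1) || any(cycle_index != floor(cycle_index)))
    stop("cycle_index must be an integer >= 1", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  amount / (1 + rate)^(cycle_index - 1)
}

#' PR program cost
#'
#' Per-session cost is the 2-hour session reimbursement plus the patient
#' copayment (both perspectives), plus round-trip travel under the societal
#' perspective: `2 * distance * cost_per_mile` with
#' `cost_per_mile = fuel price / fleet fuel economy` (defaults $2.32/gal and
#' 20 mi/gal, i.e. $0.116/mile).
#'
#' @param n_sessions session counts (vectorized, >= 0).
#' @param draw a parameter draw.
#' @param perspective `"societal"` or `"health_system"`.
#' @param distance_miles one-way distances (vectorized; default is the draw's
#'   mean travel distance).
#' @param session_cost_override optional all-in USD per session replacing
#'   every per-session component (threshold analysis).
#' @return USD per patient.
#' @export
pr_program_cost <- function(n_sessions, draw,
                            perspective = c("societal", "health_system"),
                            distance_miles = draw_value(draw, "travel_distance_miles"),
                            session_cost_override = NULL) {
  perspective <- match.arg(perspective)
  if (any(!is.finite(n_sessions)) || any(n_sessions < 0))
    stop("n_sessions must be >= 0", call. = FALSE)
  if (!is.null(session_cost_override))
    return(n_sessions * session_cost_override)
  per_session <- draw_value(draw, "pr_session_reimbursement") +
    draw_value(draw, "pr_copay_per_session")
  cost <- n_sessions * per_session
  if (perspective == "societal") {
    per_mile <- draw_value(draw, "fuel_cost_per_gallon") /
      draw_value(draw, "fleet_mpg")
    cost <- cost + n_sessions * 2 * distance_miles * per_mile
  }
  cost
}

#' Year-1 utilization costs
#'
#' Hospitalization days are costed at the daily rate for the patient's age
#' tier at the index admission (45-64, 65-84, >= 85 years); ED visits at the
#' per-visit cost; SNF days at the daily SNF cost.
#'
#' @param outcome a [simulate_year1()] data frame.
#' @param cohort the matching cohort (for the age tier).
#' @param draw a parameter draw.
#' @return data frame with columns `hospitalization`, `ed`, `snf` (USD).
#' @export
year1_utilization_costs <- function(outcome, cohort, draw) {
  stopifnot(nrow(outcome) == nrow(cohort))
  daily <- ifelse(cohort$age < 65, draw_value(draw, "hosp_cost_per_day_age45_64"),
           ifelse(cohort$age < 85, draw_value(draw, "hosp_cost_per_day_age65_84"),
                  draw_value(draw, "hosp_cost_per_day_age85plus")))
  data.frame(
    hospitalization = outcome$hospital_days * daily,
    ed = outcome$ed_visits * draw_value(draw, "ed_cost_per_visit"),
    snf = outcome$snf_days * draw_value(draw, "snf_cost_per_day")
  )
}

#' Annual COPD-attributable cost after year 1
#'
#' @param stage GOLD stage 2, 3 or 4 (vectorized).
#' @param draw a parameter draw.
#' @return USD per year.
#' @export
post_year1_annual_cost <- function(stage, draw) {
  if (!all(stage %in% c(2, 3, 4))) stop("GOLD stage must be 2, 3 or 4",
                                        call. = FALSE)
  stage_lookup(draw, "post_y1_cost_gold", as.integer(stage))
}

interval_cont <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
interval_rate <- function(p, n) {
  se <- sqrt(pmax(p * (1 - p), 0) / n)
  c(max(0, p - 1.959964 * se), min(1, p + 1.959964 * se))
}

#' Summarize a strategy run
#'
#' Cohort-level means with 95% intervals (percentile across patients for
#' accrual quantities; normal-approximation for the year-1 rates) for the
#' outcomes reported per strategy: lifetime discounted cost, QALYs,
#' unadjusted life expectancy, year-1 readmission and mortality, year-1 QALYs
#' and category costs, and post-year-1 costs.
#'
#' @param patients per-patient data frame from [run_strategy()].
#' @param name strategy label.
#' @return an object of class `strategy_result`; per-patient data kept in
#'   `$patients`.
#' @export
summarize_strategy <- function(patients, name = "strategy") {
  n <- nrow(patients)
  row <- function(metric, x, rate = FALSE) {
    m <- mean(x)
    iv <- if (rate) interval_rate(m, n) else interval_cont(x)
    data.frame(metric = metric, mean = m, lo = iv[1], hi = iv[2])
  }
  stats <- rbind(
    row("lifetime_cost_disc", patients$cost_total_disc),
    row("qalys_disc", patients$qaly_total_disc),
    row("life_expectancy", patients$years_lived),
    row("readmission_rate_y1", as.numeric(patients$readmitted), rate = TRUE),
    row("mortality_y1", as.numeric(patients$died), rate = TRUE),
    row("qaly_y1", patients$qaly_y1),
    row("cost_pr", patients$cost_pr),
    row("cost_hospitalization_y1", patients$hospitalization),
    row("cost_ed_y1", patients$ed),
    row("cost_snf_y1", patients$snf),
    row("cost_year1_total", patients$cost_year1),
    row("cost_post_y1_disc", patients$post_cost_disc),
    row("cost_post_y1_undisc", patients$post_cost_undisc)
  )
  rownames(stats) <- NULL
  structure(list(name = name, n = n, stats = stats, patients = patients),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result '%s', n = %d>\n", x$name, x$n))
  print(transform(x$stats, mean = signif(mean, 6), lo = signif(lo, 6),
                  hi = signif(hi, 6)), row.names = FALSE)
  invisible(x)
}

result_mean <- function(res, metric) {
  i <- match(metric, res$stats$metric)
  if (is.na(i)) stop("unknown metric: ", metric, call. = FALSE)
  res$stats$mean[i]
}

#' Incremental cost-effectiveness comparison
#'
#' Deltas are PR minus no PR on cohort means. PR is dominant when it costs
#' less and yields more QALYs; no PR is dominant in the mirrored case; the
#' ICER is defined only in the trade-off quadrants. Net monetary benefit is
#' `wtp * delta_qaly - delta_cost`.
#'
#' @param res_pr,res_nopr [summarize_strategy()] results for the PR and no-PR
#'   arms; must come from cohorts of the same size.
#' @param wtp willingness-to-pay, USD per QALY.
#' @return an object of class `incremental_result` with `delta_cost`,
#'   `delta_qaly`, `delta_le`, `icer`, `dominance`, `nmb`, plus per-metric
#'   deltas in `$deltas`.
#' @export
incremental_analysis <- function(res_pr, res_nopr, wtp = 50000) {
  stopifnot(inherits(res_pr, "strategy_result"),
            inherits(res_nopr, "strategy_result"))
  if (res_pr$n != res_nopr$n)
    stop("strategies were run on different cohort sizes", call. = FALSE)
  dc <- result_mean(res_pr, "lifetime_cost_disc") -
    result_mean(res_nopr, "lifetime_cost_disc")
  dq <- result_mean(res_pr, "qalys_disc") - result_mean(res_nopr, "qalys_disc")
  dle <- result_mean(res_pr, "life_expectancy") -
    result_mean(res_nopr, "life_expectancy")
  dominance <- if (dc < 0 && dq > 0) "PR dominant"
    else if (dc > 0 && dq < 0) "noPR dominant"
    else "trade-off"
  icer <- if (dominance == "trade-off" && dq != 0) dc / dq else NA_real_
  deltas <- merge(res_pr$stats[, c("metric", "mean")],
                  res_nopr$stats[, c("metric", "mean")],
                  by = "metric", suffixes = c("_pr", "_nopr"), sort = FALSE)
  deltas$difference <- deltas$mean_pr - deltas$mean_nopr
  structure(list(delta_cost = dc, delta_qaly = dq, delta_le = dle,
                 icer = icer, dominance = dominance,
                 nmb = wtp * dq - dc, wtp = wtp, deltas = deltas),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf(paste0("<incremental_result: delta cost %.0f, delta QALY %.3f, ",
                     "%s, NMB(%.0f) = %.0f>\n"),
              x$delta_cost, x$delta_qaly, x$dominance, x$wtp, x$nmb))
  invisible(x)
}

#' Run the full PR vs no-PR comparison on one cohort
#'
#' Generates a cohort, runs both strategies with common random numbers, and
#' returns the two strategy summaries plus the incremental result.
#'
#' @param n_patients cohort size.
#' @param draw a parameter draw (base case by default).
#' @param model a [mortality_model()].
#' @param population `"main"` or `"younger"`.
#' @param perspective `"societal"` or `"health_system"`.
#' @param seed integer seed.
#' @param wtp willingness-to-pay for the net monetary benefit.
#' @param pr_strategy the PR arm's [strategy_spec()] (scenario analyses pass
#'   modified specs).
#' @param pr_session_cost_override optional all-in USD per PR session.
#' @param discount_rate annual discount rate.
#' @return a list of class `pr_comparison`: `$pr`, `$nopr`
#'   ([summarize_strategy()] objects) and `$incremental`.
#' @export
run_comparison <- function(n_patients, draw = base_draw(default_registry()),
                           model = mortality_model(draw = draw),
                           population = "main",
                           perspective = c("societal", "health_system"),
                           seed = 1L, wtp = 50000,
                           pr_strategy = strategy_spec("PR"),
                           pr_session_cost_override = NULL,
                           discount_rate = draw_value(draw, "discount_rate")) {
  perspective <- match.arg(perspective)
  cohort <- generate_cohort(n_patients, draw, population, seed)
  pp_pr <- run_strategy(cohort, pr_strategy, draw, model, perspective, seed,
                        discount_rate, pr_session_cost_override)
  pp_no <- run_strategy(cohort, strategy_spec("noPR"), draw, model,
                        perspective, seed, discount_rate)
  res_pr <- summarize_strategy(pp_pr, "PR")
  res_no <- summarize_strategy(pp_no, "noPR")
  structure(list(pr = res_pr, nopr = res_no,
                 incremental = incremental_analysis(res_pr, res_no, wtp)),
            class = "pr_comparison")
}

#' @export
print.pr_comparison <- function(x, ...) {
  print(x$nopr); print(x$pr); print(x$incremental)
  invisible(x)
}
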