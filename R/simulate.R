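#' Convert an event rate to a probability
#'
#' Standard exponential conversion for a constant rate over duration `t`:
#' `1 - exp(-rate * t)`.
#'
#' @param rate events per unit time (>= 0).
#' @param t duration (>= 0).
#' @return probability of at least one event in `t`.
#' @export
rate_to_probability <- function(rate, t = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rate must be >= 0",
                                                   call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0", call. = FALSE)
  1 - exp(-rate * t)
}

#' Apply a hazard ratio to a baseline probability
#'
#' Multiplicative on the probability scale, capped at 1. The model applies
#' treatment hazard ratios directly to first-year event probabilities (the
#' published PR readmission rate equals baseline x HR on the probability
#' scale, not the rate-scale transform).
#'
#' @param p_base baseline probability in \[0, 1\].
#' @param hr hazard ratio (> 0).
#' @return `min(1, p_base * hr)`.
#' @export
apply_hazard_ratio <- function(p_base, hr) {
  if (any(!is.finite(p_base)) || any(p_base < 0 | p_base > 1))
    stop("p_base must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(hr)) || any(hr <= 0)) stop("hr must be > 0", call. = FALSE)
  pmin(1, p_base * hr)
}

#' Strategy specification
#'
#' Defines one arm of the comparison. `"noPR"` has every effect flag off.
#' Scenario analyses force individual effects off (flags) or override the
#' readmission hazard ratio.
#'
#' @param name `"PR"` or `"noPR"`.
#' @param apply_mortality_hr,apply_readmission_hr,apply_utility_increment
#'   effect flags; default on for PR, forced off for noPR.
#' @param readmission_hr_override optional positive value replacing the drawn
#'   readmission HR (e.g. 1 for the no-readmission-effect scenario).
#' @param session_mode `"observed"` (Poisson, mean 9) or `"fixed"`.
#' @param n_sessions_fixed session count in fixed mode.
#' @return an object of class `strategy_spec`.
#' @export
strategy_spec <- function(name = c("PR", "noPR"),
                          apply_mortality_hr = NULL,
                          apply_readmission_hr = NULL,
                          apply_utility_increment = NULL,
                          readmission_hr_override = NULL,
                          session_mode = c("observed", "fixed"),
                          n_sessions_fixed = 16) {
  name <- match.arg(name)
  session_mode <- match.arg(session_mode)
  is_pr <- name == "PR"
  flag <- function(x) if (is.null(x)) is_pr else isTRUE(x)
  spec <- list(name = name,
               apply_mortality_hr = flag(apply_mortality_hr) && is_pr,
               apply_readmission_hr = flag(apply_readmission_hr) && is_pr,
               apply_utility_increment = flag(apply_utility_increment) && is_pr,
               readmission_hr_override = readmission_hr_override,
               session_mode = session_mode,
               n_sessions_fixed = n_sessions_fixed)
  if (!is.null(readmission_hr_override))
    assert_scalar_num(readmission_hr_override, "readmission_hr_override",
                      lower = 1e-12)
  structure(spec, class = "strategy_spec")
}

# Shared uniform variates for year-1 events: generated once per (seed, n) and
# reused by both arms, so contrasts use common random numbers.
year1_randoms <- function(n, seed) {
  with_seed(substream_seed(seed, "year1"), list(
    u_death = stats::runif(n),
    u_readmit = stats::runif(n),
    u_hosp = stats::runif(n),
    u_ed = stats::runif(n),
    u_snf = stats::runif(n),
    u_sessions = stats::runif(n),
    u_distance = stats::runif(n)
  ))
}

stage_lookup <- function(draw, prefix, stage) {
  v <- c(draw_value(draw, paste0(prefix, "2")),
         draw_value(draw, paste0(prefix, "3")),
         draw_value(draw, paste0(prefix, "4")))
  v[stage - 1L]
}

#' Simulate first-year outcomes for a cohort
#'
#' Year-1 events conditioned on strategy: death is Bernoulli on the baseline
#' first-year mortality times the mortality HR if PR; readmission is
#' Bernoulli on the baseline readmission probability times the readmission
#' HR if PR; hospital days, ED visits and SNF days are drawn from the
#' arm-specific per-person-year gamma distributions (the arm-specific
#' distributions already embody the utilization effect of PR, so no hazard
#' ratio is applied to them); PR session counts are drawn in the PR arm only.
#' The year-1 QALY is 0 for decedents, otherwise the GOLD-stage utility plus
#' the PR utility increment (PR arm), capped at 1.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param strategy a [strategy_spec()].
#' @param draw a parameter draw.
#' @param randoms shared uniforms from `year1_randoms`; supply the same
#'   object to both arms for common-random-number contrasts.
#' @param seed used to build `randoms` when not supplied.
#' @return data frame: `died`, `readmitted`, `hospital_days`, `ed_visits`,
#'   `snf_days`, `pr_sessions`, `distance_miles`, `qaly_y1`.
#' @export
simulate_year1 <- function(cohort, strategy, draw,
                           randoms = year1_randoms(nrow(cohort), seed),
                           seed = 1L) {
  stopifnot(inherits(strategy, "strategy_spec"))
  n <- nrow(cohort)
  arm <- if (strategy$name == "PR") "pr" else "nopr"

  p_death <- min(1, max(0, draw_value(draw, "mortality_y1_nopr")))
  if (strategy$apply_mortality_hr)
    p_death <- apply_hazard_ratio(p_death, draw_value(draw, "mortality_hr_pr"))
  died <- randoms$u_death < p_death

  p_readmit <- min(1, max(0, draw_value(draw, "readmission_y1_nopr")))
  hr_r <- if (!is.null(strategy$readmission_hr_override))
    strategy$readmission_hr_override else draw_value(draw, "readmission_hr_pr")
  if (strategy$apply_readmission_hr || !is.null(strategy$readmission_hr_override))
    p_readmit <- apply_hazard_ratio(p_readmit, hr_r)
  readmitted <- randoms$u_readmit < p_readmit

  hospital_days <- dist_quantile(draw_spec(draw, paste0("hospital_days_", arm)),
                                 randoms$u_hosp)
  ed_visits <- dist_quantile(draw_spec(draw, paste0("ed_visits_", arm)),
                             randoms$u_ed)
  snf_days <- dist_quantile(draw_spec(draw, paste0("snf_days_", arm)),
                            randoms$u_snf)

  pr_sessions <- if (strategy$name == "PR") {
    if (strategy$session_mode == "fixed")
      rep(strategy$n_sessions_fixed, n)
    else
      dist_quantile(draw_spec(draw, "pr_sessions_mean"), randoms$u_sessions)
  } else rep(0, n)

  distance_miles <- dist_quantile(draw_spec(draw, "travel_distance_miles"),
                                  randoms$u_distance)

  util <- stage_lookup(draw, "utility_gold", cohort$gold_stage)
  if (strategy$apply_utility_increment)
    util <- util + draw_value(draw, "utility_pr_increment")
  qaly_y1 <- ifelse(died, 0, pmin(1, pmax(0, util)))

  data.frame(died = died, readmitted = readmitted,
             hospital_days = hospital_days, ed_visits = ed_visits,
             snf_days = snf_days, pr_sessions = pr_sessions,
             distance_miles = distance_miles, qaly_y1 = qaly_y1)
}

# Shared uniforms for post-year-1 survival, one per patient per potential
# cycle; strategy-independent dimensions so both arms share the same matrix.
post_randoms <- function(cohort, model, seed) {
  n <- nrow(cohort)
  kmax <- as.integer(model$age_cap - floor(min(c(cohort$age, model$age_cap))) + 1)
  with_seed(substream_seed(seed, "post"),
            matrix(stats::runif(n * kmax), nrow = n))
}

#' Simulate the post-year-1 life course for a cohort
#'
#' Annual cycles after the first year: a patient alive at the start of year
#' `k` (>= 2, at age `age + k - 1`) dies with [annual_mortality_probability()]
#' and otherwise accrues the GOLD-stage utility as QALYs and the
#' stage-stratified annual COPD cost, discounted at `discount_rate` with the
#' first year undiscounted. The year of death accrues nothing (no half-cycle
#' correction). GOLD stage is fixed for life; PR has no effect beyond year 1.
#'
#' @param cohort a cohort data frame.
#' @param year1 the matching [simulate_year1()] outcome.
#' @param draw a parameter draw.
#' @param model a [mortality_model()].
#' @param randoms uniform matrix from `post_randoms`; share across arms for
#'   common random numbers.
#' @param discount_rate annual discount rate (default from the draw).
#' @param seed used to build `randoms` when not supplied.
#' @return data frame: `years_lived`, `post_qaly_disc`, `post_qaly_undisc`,
#'   `post_cost_disc`, `post_cost_undisc`, `qaly_total_disc`,
#'   `qaly_total_undisc`.
#' @export
simulate_lifecourse <- function(cohort, year1, draw, model,
                                randoms = post_randoms(cohort, model, seed),
                                discount_rate = draw_value(draw, "discount_rate"),
                                seed = 1L) {
  stopifnot(nrow(cohort) == nrow(year1))
  n <- nrow(cohort)
  alive <- !year1$died
  years_lived <- as.numeric(alive)
  util <- stage_lookup(draw, "utility_gold", cohort$gold_stage)
  annual_cost <- stage_lookup(draw, "post_y1_cost_gold", cohort$gold_stage)

  post_qaly_disc <- post_qaly_undisc <- numeric(n)
  post_cost_disc <- post_cost_undisc <- numeric(n)
  kmax <- ncol(randoms) + 1L
  k <- 2L
  while (any(alive) && k <= kmax) {
    q <- annual_mortality_probability(model, cohort$age + k - 1, cohort$sex,
                                      cohort$gold_stage)
    alive <- alive & (randoms[, k - 1L] >= q)
    df <- 1 / (1 + discount_rate)^(k - 1)
    years_lived <- years_lived + alive
    post_qaly_undisc <- post_qaly_undisc + alive * util
    post_qaly_disc <- post_qaly_disc + alive * util * df
    post_cost_undisc <- post_cost_undisc + alive * annual_cost
    post_cost_disc <- post_cost_disc + alive * annual_cost * df
    k <- k + 1L
  }
  data.frame(years_lived = years_lived,
             post_qaly_disc = post_qaly_disc,
             post_qaly_undisc = post_qaly_undisc,
             post_cost_disc = post_cost_disc,
             post_cost_undisc = post_cost_undisc,
             qaly_total_disc = year1$qaly_y1 + post_qaly_disc,
             qaly_total_undisc = year1$qaly_y1 + post_qaly_undisc)
}

#' Run one strategy on a cohort
#'
#' Full patient-level pipeline: year-1 events, post-year-1 life course, and
#' cost accounting under the chosen perspective. Random streams are named
#' substreams of `seed` and do not depend on the strategy, so running both
#' arms with the same seed uses common random numbers throughout.
#'
#' @param cohort a cohort data frame.
#' @param strategy a [strategy_spec()].
#' @param draw a parameter draw.
#' @param model a [mortality_model()].
#' @param perspective `"societal"` (includes patient travel) or
#'   `"health_system"`.
#' @param seed integer seed.
#' @param discount_rate annual discount rate.
#' @param pr_session_cost_override optional all-in cost per PR session
#'   replacing reimbursement + copay + travel (used by the threshold search).
#' @return per-patient data frame with events, category costs (`cost_pr`,
#'   `cost_hospitalization`, `cost_ed`, `cost_snf`, `cost_post_disc`),
#'   `cost_total_disc`, QALY totals and `years_lived`.
#' @export
run_strategy <- function(cohort, strategy, draw, model,
                         perspective = c("societal", "health_system"),
                         seed = 1L,
                         discount_rate = draw_value(draw, "discount_rate"),
                         pr_session_cost_override = NULL) {
  perspective <- match.arg(perspective)
  y1r <- year1_randoms(nrow(cohort), seed)
  y1 <- simulate_year1(cohort, strategy, draw, randoms = y1r)
  pr <- post_randoms(cohort, model, seed)
  lc <- simulate_lifecourse(cohort, y1, draw, model, randoms = pr,
                            discount_rate = discount_rate)
  cost_pr <- pr_program_cost(y1$pr_sessions, draw, perspective,
                             distance_miles = y1$distance_miles,
                             session_cost_override = pr_session_cost_override)
  uc <- year1_utilization_costs(y1, cohort, draw)
  out <- cbind(cohort["id"], y1, lc, cost_pr = cost_pr, uc)
  out$cost_year1 <- out$cost_pr + out$hospitalization + out$ed + out$snf
  out$cost_total_disc <- out$cost_year1 + out$post_cost_disc
  out$cost_total_undisc <- out$cost_year1 + out$post_cost_undisc
  out
}
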