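population_settings <- function(population = c("main", "younger"), draw) {
  population <- match.arg(population)
  if (population == "main")
    list(mean = draw_value(draw, "age_mean_main"), lower = 60, upper = 92,
         sd = (92 - 60) / 6)
  else
    list(mean = draw_value(draw, "age_mean_sensitivity"), lower = 50, upper = 85,
         sd = (85 - 50) / 6)
}

# inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Simulated patients with the statistical structure of the modelled
#' population of Medicare beneficiaries discharged after a COPD
#' hospitalization: age from a truncated normal (main analysis: mean 77,
#' bounds 60-92, SD = range/6; younger sensitivity population: mean 65,
#' bounds 50-85), sex Bernoulli on the proportion of women (base 0.586), and
#' GOLD stage (2/3/4) categorical on the stage proportions (base
#' 0.30/0.48/0.22).
#'
#' @param n number of patients (>= 0).
#' @param draw a parameter draw ([base_draw()] or [sample_parameter_draw()]).
#' @param population `"main"` or `"younger"`.
#' @param seed integer seed; the cohort is deterministic given
#'   `(n, draw, population, seed)`.
#' @return a data frame with columns `id`, `age` (years, real), `sex`
#'   (`"female"`/`"male"`), `gold_stage` (integer 2, 3 or 4).
#' @export
generate_cohort <- function(n, draw, population = c("main", "younger"),
                            seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 0 || n != floor(n))
    stop("'n' must be a nonnegative integer", call. = FALSE)
  population <- match.arg(population)
  ps <- population_settings(population, draw)
  gp <- draw_value(draw, "gold_props")
  stopifnot(length(gp) == 3, abs(sum(gp) - 1) < 1e-8)
  pf <- draw_value(draw, "prop_female")
  with_seed(substream_seed(seed, "cohort", population), {
    age <- rtruncnorm(n, ps$mean, ps$sd, ps$lower, ps$upper)
    sex <- ifelse(stats::runif(n) < pf, "female", "male")
    gold <- c(2L, 3L, 4L)[1L + findInterval(stats::runif(n), cumsum(gp)[1:2])]
    data.frame(id = seq_len(n), age = age, sex = sex, gold_stage = gold)
  })
}

#' Sample a single patient profile
#'
#' Convenience wrapper around [generate_cohort()] for one patient.
#'
#' @inheritParams generate_cohort
#' @return a one-row patient data frame.
#' @export
sample_patient <- function(draw, population = c("main", "younger"), seed = 1L) {
  generate_cohort(1L, draw, population, seed)
}

#' Export a cohort to CSV
#'
#' @param cohort a cohort data frame from [generate_cohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_cohort <- function(cohort, path) {
  stopifnot(all(c("id", "age", "sex", "gold_stage") %in% names(cohort)))
  utils::write.csv(cohort[, c("id", "age", "sex", "gold_stage")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
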