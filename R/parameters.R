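param_entry <- function(value, dist = NULL, psa = c("none", "direct", "mean"),
                        source = "") {
  psa <- match.arg(psa)
  if (is.null(dist)) dist <- dist_spec("point", value[1])
  stopifnot(inherits(dist, "dist_spec"))
  list(value = value, dist = dist, psa = psa, source = source)
}

#' Default model parameter registry
#'
#' Every probability, utility and cost parameter of the PR vs no-PR model,
#' with its base-case value and uncertainty distribution. Base values are the
#' published point estimates; distributions are either given directly in the
#' source (beta counts, Dirichlet concentrations) or fitted here from the
#' printed mean and 95% interval ([fit_gamma_from_summary()],
#' [fit_lognormal_from_ratio()], [fit_beta_from_mean_ci()]).
#'
#' The `psa` tag on each entry controls how the probabilistic sensitivity
#' analysis samples it: `"direct"` draws from the stated distribution;
#' `"mean"` draws the sampling distribution of the mean of `n_eff`
#' observations (used for per-person-year utilization and per-accrual cost
#' gammas, whose printed intervals span patient-level heterogeneity rather
#' than uncertainty in the mean); `"none"` is held at base case.
#'
#' All monetary values are 2020 US dollars.
#'
#' @return a named list of parameter entries, class `pr_registry`.
#' @export
default_registry <- function() {
  entries <- list(
    # -- patient characteristics ------------------------------------------
    age_mean_main = param_entry(77, source = "cohort"),
    age_mean_sensitivity = param_entry(65, source = "cohort"),
    prop_female = param_entry(0.586, dist_spec("beta", c(115690, 81686)),
                              "direct", "cohort"),
    gold_props = param_entry(c(0.30, 0.48, 0.22),
                             dist_spec("dirichlet", c(75, 121, 57)),
                             "direct", "cohort"),
    # -- PR program --------------------------------------------------------
    pr_sessions_mean = param_entry(9, dist_spec("poisson", 9), "none",
                                   "PR sessions, observed"),
    pr_sessions_fixed = param_entry(16, dist_spec("point", 16,
                                                  truncation = c(8, 36)),
                                    "none", "PR sessions, fixed mode"),
    # -- year-1 utilization, per person-year (arm-specific) ----------------
    hospital_days_pr = param_entry(7.9, fit_gamma_from_summary(7.9, 0, 63),
                                   "mean", "hospital days, early PR"),
    hospital_days_nopr = param_entry(11.7,
                                     fit_gamma_from_summary(11.7, 2.3, 45.3),
                                     "mean", "hospital days, late/no PR"),
    ed_visits_pr = param_entry(1.0, fit_gamma_from_summary(1.0, 0.2, 3.8),
                               "mean", "ED visits, early PR"),
    ed_visits_nopr = param_entry(1.1, fit_gamma_from_summary(1.1, 0.2, 4.3),
                                 "mean", "ED visits, late/no PR"),
    snf_days_pr = param_entry(1.8, fit_gamma_from_summary(1.8, 0, 20),
                              "mean", "SNF days, early PR"),
    snf_days_nopr = param_entry(2.97, fit_gamma_from_summary(2.97, 0.5, 11.8),
                                "mean", "SNF days, late/no PR"),
    # -- year-1 event probabilities and effects ----------------------------
    mortality_y1_nopr = param_entry(0.141, dist_spec("beta", c(382, 2328)),
                                    "direct", "1-y mortality, no PR"),
    mortality_hr_pr = param_entry(0.50,
                                  fit_lognormal_from_ratio(0.50, 0.42, 0.59),
                                  "direct", "1-y mortality HR, early PR"),
    readmission_y1_nopr = param_entry(0.638, dist_spec("beta", c(1732, 972)),
                                      "direct", "1-y readmission, no PR"),
    readmission_hr_pr = param_entry(0.83,
                                    fit_lognormal_from_ratio(0.83, 0.77, 0.90),
                                    "direct", "1-y readmission HR, early PR"),
    # -- post-year-1 excess annual mortality by sex and GOLD stage ---------
    excess_mortality_male_gold2 = param_entry(0.0217, source = "not varied"),
    excess_mortality_male_gold3 = param_entry(0.0307, source = "not varied"),
    excess_mortality_male_gold4 = param_entry(0.0397, source = "not varied"),
    excess_mortality_female_gold2 = param_entry(0.0168, source = "not varied"),
    excess_mortality_female_gold3 = param_entry(0.02375, source = "not varied"),
    excess_mortality_female_gold4 = param_entry(0.0307, source = "not varied"),
    # -- utilities ---------------------------------------------------------
    utility_gold2 = param_entry(0.832, fit_beta_from_mean_ci(0.832, 0.821, 0.843),
                                "direct", "EQ-5D, GOLD 2"),
    utility_gold3 = param_entry(0.803, fit_beta_from_mean_ci(0.803, 0.790, 0.816),
                                "direct", "EQ-5D, GOLD 3"),
    utility_gold4 = param_entry(0.731, fit_beta_from_mean_ci(0.731, 0.699, 0.762),
                                "direct", "EQ-5D, GOLD 4"),
    utility_pr_increment = param_entry(0.065,
                                       fit_normal_from_ci(0.065, 0.047, 0.083),
                                       "direct", "utility response to PR"),
    # -- PR program costs --------------------------------------------------
    pr_session_reimbursement = param_entry(89.04, source = "2 h x $44.52/h"),
    pr_copay_per_session = param_entry(22.28, source = "copay per session"),
    travel_distance_miles = param_entry(9.9,
                                        fit_lognormal_from_ratio(9.9, 0.5, 46),
                                        "none", "one-way distance to PR"),
    fuel_cost_per_gallon = param_entry(2.32, source = "fuel"),
    fleet_mpg = param_entry(20, source = "assumed fleet fuel economy"),
    # -- health-care resource costs ----------------------------------------
    hosp_cost_per_day_age45_64 = param_entry(2385, source = "hospital $/day"),
    hosp_cost_per_day_age65_84 = param_entry(2326, source = "hospital $/day"),
    hosp_cost_per_day_age85plus = param_entry(2338, source = "hospital $/day"),
    ed_cost_per_visit = param_entry(922, fit_gamma_from_summary(922, 228, 2725),
                                    "mean", "ED $/visit"),
    snf_cost_per_day = param_entry(255, dist_spec("uniform", c(173, 500)),
                                   "direct", "SNF $/day"),
    post_y1_cost_gold2 = param_entry(3858,
                                     fit_gamma_from_summary(3858, 694, 15914),
                                     "mean", "annual COPD cost, GOLD 2"),
    post_y1_cost_gold3 = param_entry(5908,
                                     fit_gamma_from_summary(5908, 1063, 24371),
                                     "mean", "annual COPD cost, GOLD 3"),
    post_y1_cost_gold4 = param_entry(6721,
                                     fit_gamma_from_summary(6721, 1209, 27724),
                                     "mean", "annual COPD cost, GOLD 4"),
    # -- analysis settings --------------------------------------------------
    discount_rate = param_entry(0.03, source = "annual discount rate")
  )
  structure(entries, class = "pr_registry")
}

#' @export
print.pr_registry <- function(x, ...) {
  cat(sprintf("<pr_registry: %d parameters>\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-30s %s (%s)\n", nm,
                paste(signif(x[[nm]]$value, 5), collapse = "/"),
                x[[nm]]$dist$family))
  invisible(x)
}

registry_names <- function(registry) names(registry)

#' Look up one registry entry
#' @param registry a [default_registry()]-style registry.
#' @param name parameter name.
#' @return the entry (value, dist, psa, source).
#' @export
get_param <- function(registry, name) {
  if (!name %in% names(registry))
    stop("unknown parameter: ", name, call. = FALSE)
  registry[[name]]
}

#' Replace the base value of a registry entry
#'
#' The uncertainty distribution is rescaled so its mean tracks the new value
#' where the family allows it (gamma, normal, lognormal, poisson, point);
#' otherwise the value alone is replaced.
#'
#' @param registry a registry.
#' @param name parameter name.
#' @param value new base value.
#' @return the modified registry.
#' @export
set_param_value <- function(registry, name, value) {
  e <- get_param(registry, name)
  e$value <- value
  if (length(value) == 1 &&
      e$dist$family %in% c("gamma", "normal", "lognormal", "poisson", "point"))
    e$dist <- dist_rescale_mean(e$dist, value)
  registry[[name]] <- e
  registry
}

#' Base-case parameter draw
#'
#' A draw whose every entry equals its registry base value (no sampling).
#'
#' @param registry a registry.
#' @return a `pr_draw` object.
#' @export
base_draw <- function(registry) {
  values <- lapply(registry, `[[`, "value")
  structure(list(values = values, specs = lapply(registry, `[[`, "dist"),
                 sampled = character(0)),
            class = "pr_draw")
}

#' Value of one parameter in a draw
#' @param draw a `pr_draw`.
#' @param name parameter name.
#' @return numeric value (vector for `gold_props`).
#' @export
draw_value <- function(draw, name) {
  v <- draw$values[[name]]
  if (is.null(v)) stop("unknown parameter in draw: ", name, call. = FALSE)
  v
}

draw_spec <- function(draw, name) {
  s <- draw$specs[[name]]
  if (is.null(s)) stop("unknown parameter in draw: ", name, call. = FALSE)
  s
}

#' Default probabilistic-sensitivity-analysis scope
#'
#' `"standard"` covers every parameter the analysis varies probabilistically:
#' the two hazard ratios, the utility response to PR, the baseline year-1
#' mortality and readmission probabilities, the per-person-year utilization
#' means, the GOLD-stage utilities, and the cost parameters with stated
#' distributions. `"narrow"` restricts to the effect estimates alone (the two
#' hazard ratios and the utility response).
#'
#' @param registry a registry.
#' @param mode `"standard"` or `"narrow"`.
#' @return character vector of parameter names.
#' @export
default_psa_scope <- function(registry = default_registry(),
                              mode = c("standard", "narrow")) {
  mode <- match.arg(mode)
  narrow <- c("mortality_hr_pr", "readmission_hr_pr", "utility_pr_increment")
  if (mode == "narrow") return(narrow)
  c(narrow,
    "mortality_y1_nopr", "readmission_y1_nopr",
    "hospital_days_pr", "hospital_days_nopr",
    "ed_visits_pr", "ed_visits_nopr",
    "snf_days_pr", "snf_days_nopr",
    "utility_gold2", "utility_gold3", "utility_gold4",
    "ed_cost_per_visit", "snf_cost_per_day",
    "post_y1_cost_gold2", "post_y1_cost_gold3", "post_y1_cost_gold4")
}

#' Sample one parameter draw for the PSA outer loop
#'
#' Entries named in `psa_scope` are sampled from their distribution (entries
#' tagged `psa = "mean"` use the sampling distribution of the mean of `n_eff`
#' observations); all other entries are held at base case. Probabilities are
#' clamped to \[0, 1\] and nonnegative quantities to 0 after sampling. Uses
#' the current RNG state; seed with [substream_seed()] for reproducibility.
#'
#' @param registry a registry.
#' @param psa_scope character vector of parameter names to sample.
#' @param n_eff effective sample size behind published utilization and cost
#'   means (default 2704, the size of the propensity-matched source cohort).
#' @return a `pr_draw`; `draw$sampled` records which entries were sampled.
#' @export
sample_parameter_draw <- function(registry, psa_scope = default_psa_scope(registry),
                                  n_eff = 2704) {
  unknown <- setdiff(psa_scope, names(registry))
  if (length(unknown))
    stop("unknown parameter(s) in psa_scope: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  draw <- base_draw(registry)
  prob_like <- c("mortality_y1_nopr", "readmission_y1_nopr", "prop_female",
                 "utility_gold2", "utility_gold3", "utility_gold4")
  for (nm in psa_scope) {
    e <- registry[[nm]]
    if (e$dist$family == "point") next
    v <- if (e$psa == "mean" && e$dist$family == "gamma")
      sample_gamma_mean(e$dist, n_eff)
    else if (e$dist$family == "dirichlet")
      as.numeric(dist_sample(e$dist, 1))
    else dist_sample(e$dist, 1)
    if (nm %in% prob_like) v <- min(max(v, 0), 1)
    if (e$dist$family %in% c("gamma", "lognormal", "uniform")) v <- max(v, 0)
    draw$values[[nm]] <- v
    # patient-level distributions follow the drawn mean
    if (e$psa == "mean")
      draw$specs[[nm]] <- dist_rescale_mean(e$dist, v)
  }
  draw$sampled <- intersect(psa_scope, names(registry))
  draw
}

#' Serialize a registry to a flat configuration list
#'
#' One entry per parameter: `list(value = ..., distribution = family,
#' params = named numerics)`. The inverse of [apply_config_overrides()] for
#' round-tripping values.
#'
#' @param registry a registry.
#' @return a named list suitable for [yaml::write_yaml()].
#' @export
registry_to_config <- function(registry) {
  lapply(registry, function(e)
    list(value = as.numeric(e$value),
         distribution = e$dist$family,
         params = as.list(e$dist$params)))
}

#' Apply configuration overrides to a registry
#'
#' Overrides merge by parameter name: a bare number replaces the base value
#' (via [set_param_value()]); a list may carry `value` and/or `params` for
#' the distribution. Unknown keys are rejected by name.
#'
#' @param registry a registry.
#' @param overrides named list of overrides.
#' @return the modified registry.
#' @export
apply_config_overrides <- function(registry, overrides) {
  if (is.null(overrides) || !length(overrides)) return(registry)
  unknown <- setdiff(names(overrides), names(registry))
  if (length(unknown))
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (is.numeric(ov)) {
      registry <- set_param_value(registry, nm, as.numeric(ov))
    } else if (is.list(ov)) {
      if (!is.null(ov$params)) {
        e <- registry[[nm]]
        e$dist <- dist_spec(e$dist$family, unlist(ov$params), e$dist$truncation)
        registry[[nm]] <- e
      }
      if (!is.null(ov$value))
        registry <- set_param_value(registry, nm, as.numeric(ov$value))
    } else stop("override for '", nm, "' must be numeric or a list", call. = FALSE)
  }
  registry
}
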