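#' Read a period life table
#'
#' Expects a CSV with columns `age` (contiguous integers from 0),
#' `qx_female`, `qx_male` (annual all-cause death probabilities in \[0, 1\]).
#' The schema is validated strictly.
#'
#' @param path CSV path; default is the packaged synthetic US-like period
#'   life table (a Gompertz-Makeham construction at current US mortality
#'   levels, labelled synthetic because the model's original source table is
#'   not published).
#' @return a data frame `age`, `qx_female`, `qx_male`.
#' @export
read_life_table <- function(path = system.file("extdata",
                                               "life_table_synthetic.csv",
                                               package = "prcea")) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  lt <- utils::read.csv(path)
  need <- c("age", "qx_female", "qx_male")
  if (!identical(names(lt), need))
    stop("life table must have columns exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(lt$age == seq(0, nrow(lt) - 1)))
    stop("life table ages must be contiguous integers starting at 0",
         call. = FALSE)
  for (cl in c("qx_female", "qx_male"))
    if (any(!is.finite(lt[[cl]])) || any(lt[[cl]] < 0 | lt[[cl]] > 1))
      stop("life table ", cl, " must be probabilities in [0, 1]", call. = FALSE)
  lt
}

default_excess_matrix <- function(draw) {
  m <- matrix(c(draw_value(draw, "excess_mortality_female_gold2"),
                draw_value(draw, "excess_mortality_female_gold3"),
                draw_value(draw, "excess_mortality_female_gold4"),
                draw_value(draw, "excess_mortality_male_gold2"),
                draw_value(draw, "excess_mortality_male_gold3"),
                draw_value(draw, "excess_mortality_male_gold4")),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("female", "male"), c("2", "3", "4")))
  m
}

#' Post-year-1 mortality model
#'
#' Annual all-cause mortality after the first year is baseline life-table
#' mortality by age and sex plus a COPD excess by sex and GOLD stage
#' (defaults: men 2.17%-3.97%, women 1.68%-3.07% across GOLD 2-4, stage 3 at
#' the midpoint), optionally scaled by a single calibration multiplier
#' ([calibrate_excess_mortality()]). Beyond `age_cap` death is certain.
#'
#' @param life_table a [read_life_table()] data frame.
#' @param excess 2 x 3 matrix (rows `female`, `male`; columns `"2"`, `"3"`,
#'   `"4"`) of excess annual mortality, or `NULL` to build the default from
#'   `draw`.
#' @param draw parameter draw supplying the default excess rates.
#' @param multiplier positive scale factor on the excess rates.
#' @param age_cap age at and beyond which death is certain (default 110).
#' @return an object of class `mortality_model`.
#' @export
mortality_model <- function(life_table = read_life_table(), excess = NULL,
                            draw = base_draw(default_registry()),
                            multiplier = 1, age_cap = 110) {
  assert_scalar_num(multiplier, "multiplier", lower = 0)
  assert_scalar_num(age_cap, "age_cap", lower = 1)
  if (is.null(excess)) excess <- default_excess_matrix(draw)
  stopifnot(is.matrix(excess), identical(dim(excess), c(2L, 3L)),
            identical(rownames(excess), c("female", "male")),
            identical(colnames(excess), c("2", "3", "4")),
            all(excess >= 0))
  structure(list(life_table = life_table, excess = excess,
                 multiplier = multiplier, age_cap = age_cap),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("<mortality_model: excess multiplier %.4f, age cap %g>\n",
              x$multiplier, x$age_cap))
  print(signif(x$excess * x$multiplier, 4))
  invisible(x)
}

#' Annual post-year-1 mortality probability
#'
#' `min(1, baseline(age, sex) + multiplier * excess(sex, stage))`, with 1 at
#' and beyond the model's age cap. Vectorized over patients.
#'
#' @param model a [mortality_model()].
#' @param age ages in years (real; the life-table row is `floor(age)`).
#' @param sex `"female"`/`"male"`.
#' @param stage GOLD stage 2, 3 or 4.
#' @return probabilities in \[0, 1\].
#' @export
annual_mortality_probability <- function(model, age, sex, stage) {
  stopifnot(inherits(model, "mortality_model"))
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  if (!all(stage %in% c(2, 3, 4))) stop("GOLD stage must be 2, 3 or 4",
                                        call. = FALSE)
  if (!all(sex %in% c("female", "male"))) stop("sex must be female/male",
                                               call. = FALSE)
  lt <- model$life_table
  idx <- pmin(floor(age), max(lt$age)) + 1L
  base <- ifelse(sex == "female", lt$qx_female[idx], lt$qx_male[idx])
  exc <- model$multiplier * model$excess[cbind(sex, as.character(stage))]
  p <- pmin(1, base + exc)
  p[age >= model$age_cap] <- 1
  p
}

# Mean undiscounted years lived for a no-PR cohort under a mortality model:
# the calibration objective. Deterministic given (n, seed).
simulate_life_expectancy <- function(model, draw, n = 20000, seed = 1L,
                                     population = "main") {
  cohort <- generate_cohort(n, draw, population, seed)
  p_death <- min(1, draw_value(draw, "mortality_y1_nopr"))
  u1 <- with_seed(substream_seed(seed, "le-year1"), stats::runif(n))
  alive <- u1 >= p_death
  years <- as.numeric(alive)
  kmax <- as.integer(model$age_cap - floor(min(cohort$age)) + 1)
  u <- with_seed(substream_seed(seed, "le-post"),
                 matrix(stats::runif(n * kmax), nrow = n))
  k <- 2L
  while (any(alive) && k <= kmax + 1L) {
    q <- annual_mortality_probability(model, cohort$age + k - 1, cohort$sex,
                                      cohort$gold_stage)
    alive <- alive & (u[, k - 1L] >= q)
    years <- years + alive
    k <- k + 1L
  }
  mean(years)
}

#' Calibrate excess mortality to a target life expectancy
#'
#' The source's age/sex/GOLD-specific mortality table is not published, so
#' the packaged baseline life table is synthetic. This operation scales the
#' sex- and stage-specific excess rates by a single shared multiplier, found
#' by bisection, so that the simulated no-PR cohort's mean undiscounted life
#' expectancy matches `target_le` (default tolerance 0.05 years) at a fixed
#' seed.
#'
#' @param target_le target mean undiscounted life expectancy in years.
#' @param model starting [mortality_model()].
#' @param draw parameter draw (base case for calibration).
#' @param seed integer seed for the calibration cohort.
#' @param n cohort size used during calibration.
#' @param tol tolerance on life expectancy, years.
#' @param bounds multiplier search interval.
#' @return the calibrated `mortality_model`.
#' @export
calibrate_excess_mortality <- function(target_le, model, draw, seed = 1L,
                                       n = 20000, tol = 0.05,
                                       bounds = c(0.1, 10)) {
  assert_scalar_num(target_le, "target_le", lower = 0)
  le_at <- function(m) {
    model$multiplier <- m
    simulate_life_expectancy(model, draw, n = n, seed = seed)
  }
  lo <- bounds[1]; hi <- bounds[2]
  le_lo <- le_at(lo)   # LE is decreasing in the multiplier
  le_hi <- le_at(hi)
  if (le_lo < target_le - tol || le_hi > target_le + tol)
    stop(sprintf(paste0("calibration target %.3f y not attainable within ",
                        "multiplier bounds [%g, %g] (attainable LE %.3f-%.3f)"),
                 target_le, bounds[1], bounds[2], le_hi, le_lo),
         call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- le_at(mid) - target_le
    if (abs(f_mid) <= tol / 2 || (hi - lo) < 1e-6) break
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  model$multiplier <- mid
  model
}
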