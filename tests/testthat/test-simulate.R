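test_that("rate-to-probability conversion is the exponential transform", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(5, 0), 0)
  # round-trip of the 63.8% first-year readmission probability
  expect_equal(rate_to_probability(1.0164, 1), 0.6381, tolerance = 1e-4)
  expect_equal(rate_to_probability(-log(1 - 0.638)), 0.638)
  expect_error(rate_to_probability(-1, 1))
  expect_error(rate_to_probability(1, -1))
})

test_that("hazard ratios act multiplicatively on the probability scale", {
  expect_equal(apply_hazard_ratio(0.638, 0.83), 0.52954)
  expect_equal(apply_hazard_ratio(0.25, 1), 0.25)
  expect_equal(apply_hazard_ratio(0.9, 1.5), 1)      # capped
  expect_error(apply_hazard_ratio(1.2, 0.8))
  expect_error(apply_hazard_ratio(0.5, 0))
})

test_that("the no-PR strategy has every effect flag off", {
  st <- strategy_spec("noPR", apply_mortality_hr = TRUE,
                      apply_readmission_hr = TRUE,
                      apply_utility_increment = TRUE)
  expect_false(st$apply_mortality_hr)
  expect_false(st$apply_readmission_hr)
  expect_false(st$apply_utility_increment)
})

test_that("year-1 QALYs match the survival-weighted utility mixture", {
  cohort <- generate_cohort(100000, the_draw, seed = 12)
  y1 <- simulate_year1(cohort, strategy_spec("noPR"), the_draw, seed = 12)
  # analytic: (1 - 0.141) * (0.30*0.832 + 0.48*0.803 + 0.22*0.731) = 0.6836
  analytic <- (1 - 0.141) * sum(c(0.30, 0.48, 0.22) * c(0.832, 0.803, 0.731))
  expect_equal(mean(y1$qaly_y1), analytic, tolerance = 0.01)
  expect_true(all(y1$qaly_y1[y1$died] == 0))
  expect_true(all(y1$hospital_days >= 0 & y1$ed_visits >= 0 & y1$snf_days >= 0))
  expect_true(all(y1$pr_sessions == 0))
})

test_that("a PR arm with all effects off equals the no-PR arm under CRN", {
  cohort <- generate_cohort(5000, the_draw, seed = 77)
  null_pr <- strategy_spec("PR", apply_mortality_hr = FALSE,
                           apply_readmission_hr = FALSE,
                           apply_utility_increment = FALSE)
  # null-effect equivalence also needs identical utilization distributions
  reg_eq <- set_param_value(the_registry, "hospital_days_pr", 11.7)
  reg_eq$hospital_days_pr$dist <- reg_eq$hospital_days_nopr$dist
  reg_eq <- set_param_value(reg_eq, "ed_visits_pr", 1.1)
  reg_eq$ed_visits_pr$dist <- reg_eq$ed_visits_nopr$dist
  reg_eq <- set_param_value(reg_eq, "snf_days_pr", 2.97)
  reg_eq$snf_days_pr$dist <- reg_eq$snf_days_nopr$dist
  d_eq <- base_draw(reg_eq)
  pp_pr <- run_strategy(cohort, null_pr, d_eq, the_model, seed = 77)
  pp_no <- run_strategy(cohort, strategy_spec("noPR"), d_eq, the_model, seed = 77)
  for (cl in c("died", "readmitted", "hospital_days", "ed_visits", "snf_days",
               "qaly_y1", "years_lived", "qaly_total_disc", "hospitalization",
               "ed", "snf", "post_cost_disc"))
    expect_equal(pp_pr[[cl]], pp_no[[cl]], info = cl)
  # trajectories identical except for the PR program cost
  expect_equal(pp_pr$cost_total_disc - pp_no$cost_total_disc, pp_pr$cost_pr)
})

test_that("lowering the mortality HR weakly increases PR life expectancy and QALYs", {
  means <- sapply(c(0.9, 0.7, 0.5, 0.3), function(hr) {
    reg <- set_param_value(the_registry, "mortality_hr_pr", hr)
    cmp <- run_comparison(4000, base_draw(reg), the_model, seed = 5)
    c(stat_of(cmp$pr, "life_expectancy"), stat_of(cmp$pr, "qalys_disc"))
  })
  expect_true(all(diff(means[1, ]) >= 0))
  expect_true(all(diff(means[2, ]) >= 0))
})

test_that("annual mortality is capped, monotone in age, and stage-additive", {
  expect_equal(annual_mortality_probability(the_model, 110, "male", 3), 1)
  expect_equal(annual_mortality_probability(the_model, 115, "female", 2), 1)
  ages <- 60:109
  for (sx in c("female", "male")) {
    p <- annual_mortality_probability(the_model, ages, rep(sx, length(ages)),
                                      rep(4L, length(ages)))
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  lt <- read_life_table()
  base <- lt$qx_male[lt$age == 80]
  expect_equal(annual_mortality_probability(the_model, 80, "male", 4),
               base + 0.0397)
  expect_error(annual_mortality_probability(the_model, 80, "male", 5))
})

test_that("life course accounting identities hold per patient", {
  cohort <- generate_cohort(2000, the_draw, seed = 21)
  y1 <- simulate_year1(cohort, strategy_spec("noPR"), the_draw, seed = 21)
  lc <- simulate_lifecourse(cohort, y1, the_draw, the_model, seed = 21)
  # undiscounted post-year-1 QALYs = post-year-1 years lived x stage utility
  util <- c(0.832, 0.803, 0.731)[cohort$gold_stage - 1L]
  post_years <- pmax(lc$years_lived - 1, 0) * (!y1$died)
  expect_equal(lc$post_qaly_undisc, post_years * util, tolerance = 1e-12)
  # QALY total bounded by years lived; discounted <= undiscounted
  expect_true(all(lc$qaly_total_undisc <= lc$years_lived + 1e-12))
  expect_true(all(lc$post_qaly_disc <= lc$post_qaly_undisc + 1e-12))
  expect_true(all(lc$post_cost_disc <= lc$post_cost_undisc + 1e-12))
  # certain post-year-1 death: survivors live exactly one year
  lethal <- mortality_model(excess = matrix(1, 2, 3,
                              dimnames = list(c("female", "male"),
                                              c("2", "3", "4"))),
                            draw = the_draw)
  lc2 <- simulate_lifecourse(cohort, y1, the_draw, lethal, seed = 21)
  expect_true(all(lc2$years_lived == as.numeric(!y1$died)))
})

test_that("excess-mortality calibration hits its target and is monotone", {
  # fixed point: recalibrating to the model's own LE returns multiplier ~ 1
  le0 <- prcea:::simulate_life_expectancy(the_model, the_draw, n = 8000,
                                          seed = 13)
  cal0 <- calibrate_excess_mortality(le0, the_model, the_draw, seed = 13,
                                     n = 8000)
  expect_equal(cal0$multiplier, 1, tolerance = 0.15)
  # a larger target LE needs a smaller multiplier
  cal_lo <- calibrate_excess_mortality(le0 - 0.5, the_model, the_draw,
                                       seed = 13, n = 8000)
  cal_hi <- calibrate_excess_mortality(le0 + 0.5, the_model, the_draw,
                                       seed = 13, n = 8000)
  expect_lt(cal_hi$multiplier, cal_lo$multiplier)
  # target 8.85 reproduced within 0.05 y on a fresh seed
  cal <- calibrate_excess_mortality(8.85, the_model, the_draw, seed = 17,
                                    n = 20000)
  le_fresh <- prcea:::simulate_life_expectancy(cal, the_draw, n = 50000,
                                               seed = 901)
  expect_lt(abs(le_fresh - 8.85), 0.05)
  # unattainable target errors out
  expect_error(calibrate_excess_mortality(50, the_model, the_draw,
                                          seed = 13, n = 2000),
               "not attainable")
})
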