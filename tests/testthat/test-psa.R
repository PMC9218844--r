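test_that("an empty PSA scope has zero between-draw variance", {
  psa <- run_psa(5, 400, the_registry, psa_scope = character(0),
                 seed = 60, model = the_model)
  expect_equal(var(psa$draws$delta_cost), 0)
  expect_equal(var(psa$draws$delta_qaly), 0)
  expect_error(run_psa(5, 400, the_registry, wtp_grid = numeric(0), seed = 1))
})

test_that("a single draw with empty scope reduces to the base-case run", {
  psa <- run_psa(1, 800, the_registry, psa_scope = character(0),
                 seed = 61, model = the_model)
  cmp <- run_comparison(800, the_draw, the_model,
                        seed = substream_seed(61, "inner"))
  expect_equal(psa$draws$delta_cost, cmp$incremental$delta_cost)
  expect_equal(psa$draws$delta_qaly, cmp$incremental$delta_qaly)
})

test_that("nulling every PR effect leaves no dominant draws", {
  reg <- set_param_value(the_registry, "mortality_hr_pr", 1)
  reg <- set_param_value(reg, "readmission_hr_pr", 1)
  reg <- set_param_value(reg, "utility_pr_increment", 0)
  # identical utilization distributions across arms
  for (q in c("hospital_days", "ed_visits", "snf_days")) {
    reg[[paste0(q, "_pr")]] <- reg[[paste0(q, "_nopr")]]
  }
  psa <- run_psa(20, 500, reg, psa_scope = character(0), seed = 62,
                 model = the_model)
  # PR adds program cost with no benefit: never dominant
  expect_equal(psa$prob_pr_dominant, 0)
  expect_true(all(psa$draws$delta_cost > 0))
})

test_that("CEAC endpoints equal the dominance-quadrant probabilities", {
  psa <- run_psa(40, 500, the_registry,
                 wtp_grid = c(0, 50000, 1e9), seed = 63, model = the_model)
  expect_equal(psa$ceac$prob_pr_optimal[psa$ceac$wtp == 0],
               mean(psa$draws$delta_cost < 0))
  # wtp -> infinity: probability PR gains QALYs
  expect_equal(psa$ceac$prob_pr_optimal[psa$ceac$wtp == 1e9],
               mean(psa$draws$delta_qaly > 0))
  expect_true(all(psa$ceac$prob_pr_optimal >= 0 & psa$ceac$prob_pr_optimal <= 1))
  expect_lte(psa$pi_delta_cost[1], psa$pi_delta_cost[2])
  expect_lte(psa$pi_delta_qaly[1], psa$pi_delta_qaly[2])
})

test_that("PSA prediction interval covers the base-case incremental QALYs", {
  psa <- run_psa(60, 1000, the_registry, seed = 64, model = the_model)
  # base case under the same inner-seed protocol as the PSA
  cmp <- run_comparison(1000, the_draw, the_model,
                        seed = substream_seed(64, "inner"))
  expect_gte(cmp$incremental$delta_qaly, psa$pi_delta_qaly[1])
  expect_lte(cmp$incremental$delta_qaly, psa$pi_delta_qaly[2])
})

test_that("pinning a parameter at its base value reproduces the base result", {
  ows <- one_way_sensitivity("snf_cost_per_day", 255, 500, n_inner = 1500,
                             seed = 65, registry = the_registry,
                             model = the_model)
  base <- run_comparison(1500, the_draw, the_model, seed = 65)
  expect_equal(ows$low$incremental$delta_cost, base$incremental$delta_cost)
  expect_equal(ows$low$incremental$delta_qaly, base$incremental$delta_qaly)
  expect_error(one_way_sensitivity("not_a_param", 0, 1, n_inner = 100))
})

test_that("varying fixed session count shifts cost by the per-session price", {
  ows <- one_way_sensitivity("pr_sessions_fixed", 8, 36, n_inner = 2000,
                             seed = 66, registry = the_registry,
                             model = the_model)
  # same patients (CRN): extra cost = 28 sessions x mean all-in session cost
  pp <- ows$high$pr$patients
  per_session <- 111.32 + 2 * pp$distance_miles * 2.32 / 20
  expect_equal(ows$high$incremental$delta_cost - ows$low$incremental$delta_cost,
               28 * mean(per_session), tolerance = 1e-9)
  # outcomes unchanged by session count (no dose-response modelled)
  expect_equal(ows$high$incremental$delta_qaly, ows$low$incremental$delta_qaly)
})

test_that("PR stays dominant when key parameters are varied one at a time", {
  bounds <- list(mortality_hr_pr = c(0.42, 0.59),
                 readmission_hr_pr = c(0.77, 0.90),
                 utility_pr_increment = c(0.047, 0.083),
                 snf_cost_per_day = c(173, 500),
                 prop_female = c(0.3, 0.9))
  for (nm in names(bounds)) {
    ows <- one_way_sensitivity(nm, bounds[[nm]][1], bounds[[nm]][2],
                               n_inner = 3000, seed = 67,
                               registry = the_registry, model = the_model)
    expect_identical(ows$low$incremental$dominance, "PR dominant", info = nm)
    expect_identical(ows$high$incremental$dominance, "PR dominant", info = nm)
  }
})

test_that("scenario flags null individual PR effects", {
  # drop utility + mortality effects: QALY gain vanishes, PR still cost saving
  cmp2 <- scenario_analysis(scenario_flags(drop_utility_effect = TRUE,
                                           drop_mortality_effect = TRUE),
                            n_inner = 8000, seed = 68,
                            registry = the_registry, model = the_model)
  expect_lt(abs(cmp2$incremental$delta_qaly), 0.02)
  expect_lt(cmp2$incremental$delta_cost, 0)
  # additionally force readmission HR to 1 and equalize utilization:
  # delta cost = +PR program cost exactly under common random numbers
  reg <- the_registry
  for (q in c("hospital_days", "ed_visits", "snf_days"))
    reg[[paste0(q, "_pr")]] <- reg[[paste0(q, "_nopr")]]
  cmp3 <- scenario_analysis(scenario_flags(drop_utility_effect = TRUE,
                                           drop_mortality_effect = TRUE,
                                           readmission_hr_override = 1),
                            n_inner = 4000, seed = 69,
                            registry = reg, model = the_model)
  expect_equal(cmp3$incremental$delta_cost, stat_of(cmp3$pr, "cost_pr"),
               tolerance = 1e-9)
  expect_equal(cmp3$incremental$delta_qaly, 0)
})

test_that("session-cost thresholds exist and are strictly ordered", {
  th_cs <- threshold_cost_per_session("cost_saving", n_inner = 2000,
                                      seed = 70, registry = the_registry,
                                      model = the_model)
  th_50 <- threshold_cost_per_session("icer_50k", n_inner = 2000,
                                      seed = 70, registry = the_registry,
                                      model = the_model)
  th_100 <- threshold_cost_per_session("icer_100k", n_inner = 2000,
                                       seed = 70, registry = the_registry,
                                       model = the_model)
  expect_lt(th_cs, th_50)
  expect_lt(th_50, th_100)
  expect_gt(th_cs, 0)
})

test_that("with PR effects nulled any positive session cost loses", {
  reg <- the_registry
  for (q in c("hospital_days", "ed_visits", "snf_days"))
    reg[[paste0(q, "_pr")]] <- reg[[paste0(q, "_nopr")]]
  th <- threshold_cost_per_session("cost_saving", n_inner = 1000, seed = 71,
                                   registry = reg, model = the_model,
                                   flags = scenario_flags(
                                     drop_utility_effect = TRUE,
                                     drop_mortality_effect = TRUE,
                                     readmission_hr_override = 1))
  expect_lt(th, 1)
})
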