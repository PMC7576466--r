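test_that("conservation limit: no mortality, no incidence, no discounting", {
  lt <- constant_life_table(0, 20, 120)
  arm <- markov_arm("ideal", incidence = 0, recovery = 0,
                    utility_baseline = 1, utility_deteriorated = 1,
                    cost_baseline = 0, cost_deteriorated = 0,
                    rr_baseline = 1, rr_deteriorated = 1)
  tr <- run_arm(arm, econ_config(discount_effects = 0, discount_costs = 0,
                                 horizon = 10, start_age = 30), lt)
  expect_equal(tr$total_qalys, 10)
  expect_equal(tr$total_costs, 0)
  expect_equal(unname(tr$occupancy[11, ]), c(1, 0, 0))
})

test_that("closed-form discounted life-years matches hand values and the geometric sum", {
  expect_equal(closed_form_dly(1, 0, 40), 40)
  expect_equal(closed_form_dly(0.9, 0.03, 40), 6.8918, tolerance = 1e-4)
  for (s in c(0.5, 0.9, 0.99)) for (d in c(0, 0.03, 0.1)) {
    expect_equal(closed_form_dly(s, d, 25), sum((s / (1 + d))^(1:25)),
                 tolerance = 1e-12)
  }
  # s*v -> 1 limit returns the horizon
  expect_equal(closed_form_dly(1, 0, 17), 17)
})

test_that("engine reproduces the closed form under a constant-hazard table", {
  lt <- constant_life_table(0.1, 20, 150)
  arm <- markov_arm("const", incidence = 0, recovery = 0,
                    utility_baseline = 1, utility_deteriorated = 1,
                    cost_baseline = 0, cost_deteriorated = 0,
                    rr_baseline = 1, rr_deteriorated = 1)
  econ <- econ_config(discount_effects = 0.03, discount_costs = 0.03,
                      horizon = 40, start_age = 30)
  tr <- run_arm(arm, econ, lt)
  expect_equal(tr$total_qalys, closed_form_dly(0.9, 0.03, 40),
               tolerance = 1e-10)
  expect_equal(tr$total_disc_life_years, closed_form_dly(0.9, 0.03, 40),
               tolerance = 1e-10)
})

test_that("engine equals the independent transition-matrix oracle on random cases", {
  set.seed(2024)
  for (i in 1:100) {
    case <- random_markov_case()
    tr <- run_arm(case$arm, case$econ, case$lt)
    or <- oracle_run_arm(case$arm, case$econ, case$lt)
    expect_equal(tr$total_qalys, or$total_qalys, tolerance = 1e-10)
    expect_equal(tr$total_costs, or$total_costs, tolerance = 1e-10)
    expect_equal(tr$total_disc_life_years, or$total_disc_life_years,
                 tolerance = 1e-10)
  }
})

test_that("occupancy is conserved and death is absorbing on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    case <- random_markov_case()
    tr <- run_arm(case$arm, case$econ, case$lt)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-12))
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
})

test_that("discounting, utilities and mortality move totals monotonically", {
  inputs <- default_model_inputs()
  lt <- default_life_table()
  base <- run_arm(inputs$intervention, econ_config(), lt)

  hi_disc <- run_arm(inputs$intervention,
                     econ_config(discount_effects = 0.05, discount_costs = 0.05),
                     lt)
  expect_lt(hi_disc$total_qalys, base$total_qalys)
  expect_lt(hi_disc$total_costs, base$total_costs)

  arm_u <- inputs$intervention
  arm_u$utility_baseline <- min(1, arm_u$utility_baseline + 0.1)
  expect_gt(run_arm(arm_u, econ_config(), lt)$total_qalys, base$total_qalys)

  arm_rr <- inputs$intervention
  arm_rr$rr_baseline <- arm_rr$rr_deteriorated <- 1.5
  expect_lt(run_arm(arm_rr, econ_config(), lt)$total_disc_life_years,
            base$total_disc_life_years)
})

test_that("half-cycle correction adds part of the entry-state reward", {
  lt <- constant_life_table(0.1, 20, 150)
  arm <- markov_arm("const", incidence = 0, recovery = 0,
                    utility_baseline = 1, utility_deteriorated = 1,
                    cost_baseline = 100, cost_deteriorated = 100,
                    rr_baseline = 1, rr_deteriorated = 1)
  plain <- run_arm(arm, econ_config(horizon = 20, start_age = 30), lt)
  hcc <- run_arm(arm, econ_config(horizon = 20, start_age = 30,
                                  half_cycle_correction = TRUE), lt)
  expect_gt(hcc$total_qalys, plain$total_qalys)  # survival declines over a cycle
  # mean-occupancy convention: each cycle reward averages start and end
  expect_equal(hcc$total_qalys,
               sum(((0.9^(0:19) + 0.9^(1:20)) / 2) * 1.03^-(1:20)),
               tolerance = 1e-10)
})

test_that("the engine rejects a life table that misses the start age", {
  lt <- constant_life_table(0.1, 60, 100)
  arm <- default_model_inputs()$intervention
  expect_error(run_arm(arm, econ_config(start_age = 40), lt),
               "does not cover start age")
})
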