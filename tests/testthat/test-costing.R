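test_that("contact costs multiply duration by the class wage", {
  uc <- unit_costs()
  gp <- data.frame(professional = "gp", setting = "home_visit", duration = 0.5)
  expect_equal(contact_cost(gp, uc), 0.5 * 29.23)
  expect_equal(round(contact_cost(gp, uc), 2), 14.62)

  nurse3 <- data.frame(professional = rep("nurse", 3),
                       setting = rep("home_visit", 3), duration = 0.5)
  expect_equal(sum(contact_cost(nurse3, uc)), 31.185)

  # volunteer care is unmonetized
  vol <- data.frame(professional = "volunteer", setting = "home_visit",
                    duration = 3)
  expect_equal(contact_cost(vol, uc), 0)

  # missing durations fall back to the setting defaults
  tel <- data.frame(professional = "gp", setting = "telephone",
                    duration = NA_real_)
  expect_equal(contact_cost(tel, uc), 0.17 * 29.23)

  expect_error(contact_cost(data.frame(professional = "faith_healer",
                                       setting = "other", duration = 1), uc),
               "no wage rule")
})

test_that("hospital and citizen-time costs are simple linear monetizations", {
  expect_equal(hospital_cost(0), 0)
  expect_equal(hospital_cost(5), 3667.80)
  expect_equal(round(hospital_cost(12.9), 2), 9462.92)
  expect_error(hospital_cost(-1), ">= 0")

  expect_equal(citizen_time_cost(0), 0)
  expect_equal(citizen_time_cost(2), 12.14)
  expect_equal(citizen_time_cost(100), 607.00)
  expect_error(citizen_time_cost(-2), ">= 0")
})

test_that("annualization is exact and invertible", {
  expect_equal(annualize(1000, 12), 1000)
  expect_equal(annualize(1000, 8), 1500)
  expect_equal(annualize(0, 8), 0)
  for (m in c(1, 6, 8, 18)) {
    x <- 1234.56
    expect_equal(annualize(x * m / 12, m), x, tolerance = 1e-12)
  }
  expect_error(annualize(10, 0), "> 0")
})

test_that("monetization is linear in the record list", {
  set.seed(8)
  recs <- data.frame(
    professional = sample(c("gp", "nurse", "social_worker"), 30, replace = TRUE),
    setting = sample(names(default_contact_durations()), 30, replace = TRUE),
    duration = runif(30, 0.1, 2))
  expect_equal(sum(contact_cost(recs)),
               sum(contact_cost(recs[1:12, ])) + sum(contact_cost(recs[13:30, ])),
               tolerance = 1e-12)
})

test_that("currency-scale invariance: k-scaled unit costs scale every output", {
  k <- 2.5
  uc <- unit_costs()
  uck <- unit_costs(wage_physician = k * 29.23, wage_nurse = k * 20.79,
                    wage_social = k * 18.19, wage_citizen = k * 6.07,
                    bed_day = k * 733.56)
  coh <- generate_cohort(tiny_cohort_config(seed = 14))
  for (persp in c("healthcare", "societal")) {
    a <- patient_perspective_costs(coh, uc, persp)
    b <- patient_perspective_costs(coh, uck, persp)
    expect_equal(b$total, k * a$total, tolerance = 1e-9)
  }
})

test_that("perspective rules: time and travel enter only the societal view", {
  coh <- generate_cohort(tiny_cohort_config(seed = 16))
  hc <- patient_perspective_costs(coh, perspective = "healthcare")
  so <- patient_perspective_costs(coh, perspective = "societal")
  expect_true(all(hc$time_cost == 0 & hc$travel_cost == 0))
  expect_true(all(so$total >= hc$total - 1e-9))
  # intervention patients carry platform time; comparator patients travel
  expect_true(all(so$time_cost[so$arm == "intervention"] > 0))
  expect_true(all(so$time_cost[so$arm == "comparator"] == 0))
  expect_true(all(so$travel_cost[so$arm == "intervention"] == 0))

  # empty cohort: a patient with no records costs nothing under healthcare
  empty <- bernoulli_cohort(3, 0, seed = 5)
  pc <- patient_perspective_costs(empty, perspective = "healthcare")
  expect_equal(pc$total, rep(0, 3))
})

test_that("comparator travel burden follows the per-contact rule", {
  # 10 attended out-of-home contacts at 0.5 h citizen time + 2 EUR each,
  # over 12 months: healthcare total + 10 * (0.5 * 6.07 + 2) = +50.35
  coh <- bernoulli_cohort(1, 0, seed = 6)
  coh$patients$arm <- "comparator"
  coh$patients$id <- "comparator_0001"
  coh$patients$followup_months <- 12
  coh$contacts <- data.frame(patient_id = "comparator_0001",
                             professional = rep("gp", 10),
                             setting = rep("out_of_home", 10),
                             planned = TRUE, duration = 0.33)
  uc <- unit_costs(travel_cost_per_contact = 2)
  hc <- patient_perspective_costs(coh, uc, "healthcare")
  so <- patient_perspective_costs(coh, uc, "societal")
  expect_equal(so$total - hc$total, 10 * (0.5 * 6.07 + 2), tolerance = 1e-9)
})

test_that("state-conditional costs are stratum means with flagged empties", {
  pc <- data.frame(patient_id = c("a", "b", "c"), arm = "intervention",
                   contact_cost = 0, hospital_cost = 0, time_cost = 0,
                   travel_cost = 0, total = c(1000, 2000, 3000))
  cls <- c("stable_or_improved", "stable_or_improved", "worsened")
  scc <- state_conditional_costs(pc, cls)
  expect_equal(scc$mean_cost[scc$state == "baseline"], 1500)
  expect_equal(scc$mean_cost[scc$state == "deteriorated"], 3000)
  expect_equal(scc$n, c(2, 1))

  scc2 <- state_conditional_costs(pc, rep("stable_or_improved", 3))
  expect_true(is.na(scc2$mean_cost[scc2$state == "deteriorated"]))
  expect_true(scc2$empty[scc2$state == "deteriorated"])
})

test_that("programme costs fall on the intervention arm only", {
  expect_equal(arm_program_costs(program_costs(), "comparator"),
               c(one_off = 0, recurring = 0))
  expect_equal(arm_program_costs(program_costs(), "intervention"),
               c(one_off = 1268.89, recurring = 230.40))
  expect_equal(arm_program_costs(program_costs(one_off = 0), "intervention"),
               c(one_off = 0, recurring = 230.40))
})
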