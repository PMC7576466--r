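test_that("generation is deterministic given the seed", {
  cfg <- tiny_cohort_config(seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$contacts, c2$contacts)
  expect_identical(c1$admissions, c2$admissions)
  c3 <- generate_cohort(tiny_cohort_config(seed = 12))
  expect_false(identical(c1$patients, c3$patients))
})

test_that("enlarging an arm appends patients without perturbing earlier ones", {
  small <- generate_cohort(default_cohort_config(5, 5, seed = 3))
  big <- generate_cohort(default_cohort_config(5, 9, seed = 3))
  expect_identical(small$patients[small$patients$arm == "intervention", ],
                   big$patients[big$patients$arm == "intervention", ][1:5, ])
  comp_small <- small$patients[small$patients$arm == "comparator", ]
  comp_big <- big$patients[big$patients$arm == "comparator", ][1:5, ]
  rownames(comp_small) <- rownames(comp_big) <- NULL
  expect_identical(comp_small, comp_big)
})

test_that("arm sizes and patient invariants hold", {
  coh <- generate_cohort(default_cohort_config(98, 100, seed = 5))
  p <- coh$patients
  expect_equal(nrow(p), 198)
  expect_equal(sum(p$arm == "intervention"), 98)
  expect_equal(sum(p$arm == "comparator"), 100)
  for (col in c("barthel_0", "barthel_1")) {
    expect_true(all(p[[col]] >= 0 & p[[col]] <= 100))
    expect_true(all(p[[col]] %% 5 == 0))
  }
  expect_true(all(p$iadl_0 >= 0 & p$iadl_0 <= 8 & p$iadl_1 >= 0 & p$iadl_1 <= 8))
  expect_true(all(p$gds_0 >= 0 & p$gds_0 <= 15 & p$gds_1 >= 0 & p$gds_1 <= 15))
  expect_true(all(p$age >= 65))
  expect_true(all(coh$contacts$duration > 0))
  expect_true(all(coh$admissions$bed_days >= 0))
})

test_that("score sampling respects ranges, grids and degenerate parameters", {
  set.seed(1)
  # zero change: final equals baseline exactly
  tr <- sample_score_trajectory(50, c(40, 20), c(0, 0), "barthel")
  expect_equal(tr$final, tr$baseline)
  # ceiling: from the top of the range a positive mean change stays clipped
  tr2 <- sample_score_trajectory(50, c(100, 0), c(30, 1), "barthel")
  expect_true(all(tr2$baseline == 100))
  expect_true(all(tr2$final == 100))
  # extreme negative changes floor at 0, never leave the range
  tr3 <- sample_score_trajectory(200, c(10, 30), c(-60, 40), "gds")
  expect_true(all(tr3$final >= 0 & tr3$final <= 15))
})

test_that("generated moments recover the configured distributions (3 SE)", {
  cfg <- default_cohort_config(5000, 5000, seed = 101)
  coh <- generate_cohort(cfg)
  n <- 5000
  for (arm in c("intervention", "comparator")) {
    acf <- cfg[[arm]]
    p <- coh$patients[coh$patients$arm == arm, ]

    # comorbidity prevalences: binomial standard errors
    for (cm in c("congestive_heart_failure", "cerebrovascular_disease",
                 "malignancy")) {
      prev <- acf$comorbidity_prevalence[[cm]]
      se <- sqrt(prev * (1 - prev) / n)
      expect_lt(abs(mean(p[[paste0("cm_", cm)]]) - prev), 3 * se)
    }

    # age: Gaussian floored at 65; oracle is the clipped-normal mean
    mu_age <- clipped_normal_mean(acf$age_mean, acf$age_sd, 65, Inf)
    expect_lt(abs(mean(p$age) - mu_age), 3 * acf$age_sd / sqrt(n))

    # baseline scores: clipped-normal oracle per instrument
    for (ins in c("barthel", "iadl", "gds")) {
      g <- switch(ins, barthel = c(0, 100), iadl = c(0, 8), gds = c(0, 15))
      par <- acf$score_baseline[[ins]]
      mu <- clipped_normal_mean(par[1], par[2], g[1], g[2])
      expect_lt(abs(mean(p[[paste0(ins, "_0")]]) - mu),
                3 * par[2] / sqrt(n) + 0.05)  # grid-rounding residual
    }

    # contact counts: Poisson with the follow-up-scaled rate
    lambda <- acf$contact_rate * cfg$followup_months / 12
    n_contacts <- tabulate(factor(coh$contacts$patient_id, levels = p$id),
                           nbins = n)
    expect_lt(abs(mean(n_contacts) - lambda), 3 * sqrt(lambda / n))
  }
})

test_that("mean follow-up change is recovered within 3 SE away from boundaries", {
  cfg <- default_cohort_config(10000, 2, seed = 77)
  cfg$intervention$score_baseline$barthel <- c(50, 15)
  cfg$intervention$score_change$barthel <- c(-3.23, 10.7)
  coh <- generate_cohort(cfg)
  p <- coh$patients[coh$patients$arm == "intervention", ]
  d <- p$barthel_1 - p$barthel_0
  expect_lt(abs(mean(d) - (-3.23)), 3 * 10.7 / sqrt(10000) + 0.05)
})

test_that("charlson scoring sums standard weights and rejects unknown flags", {
  expect_equal(charlson_score(character(0)), 0)
  expect_equal(charlson_score(c("myocardial_infarction",
                                "congestive_heart_failure")), 2)
  expect_equal(charlson_score("metastatic_solid_tumor"), 6)
  w0 <- setNames(rep(0L, 16), names(charlson_weights()))
  expect_equal(charlson_score(names(w0), weights = w0), 0)
  expect_error(charlson_score("common_cold"), "unknown comorbidity")
})

test_that("invalid configurations are rejected naming the offending field", {
  cfg <- default_cohort_config()
  bad <- cfg$intervention
  bad$female_fraction <- 1.4
  expect_error(do.call(arm_cohort_config, unclass(bad)), "female_fraction")
  bad2 <- cfg$intervention
  bad2$comorbidity_prevalence[["dementia"]] <- -0.1
  expect_error(do.call(arm_cohort_config, unclass(bad2)),
               "comorbidity_prevalence")
  expect_error(cohort_config(cfg$intervention, cfg$comparator,
                             followup_months = 0), "followup_months")
})

test_that("cohorts round-trip through delimited text", {
  coh <- generate_cohort(tiny_cohort_config(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients, coh$patients)
  expect_equal(back$contacts, coh$contacts)
  expect_equal(back$admissions, coh$admissions)
})
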