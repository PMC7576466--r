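test_that("paired mean change matches hand-computed t intervals", {
  # differences {1,2,3}: mean 2, t(2) quantile 4.302653, CI 2 +/- 2.484138
  cs <- mean_change_ci(c(0, 0, 0), c(1, 2, 3))
  expect_equal(cs$mean_change, 2)
  expect_equal(cs$ci_low, 2 - qt(0.975, 2) / sqrt(3), tolerance = 1e-12)
  expect_equal(cs$ci_low, -0.4841, tolerance = 1e-4)
  expect_equal(cs$ci_high, 4.4841, tolerance = 1e-4)

  # zero-variance convention
  cs0 <- mean_change_ci(c(5, 7, 9), c(5, 7, 9))
  expect_equal(cs0$mean_change, 0)
  expect_equal(c(cs0$ci_low, cs0$ci_high), c(0, 0))
  expect_equal(cs0$p_value, 1)
  cs1 <- mean_change_ci(c(5, 7, 9), c(6, 8, 10))
  expect_equal(cs1$p_value, 0)

  expect_error(mean_change_ci(1, 2), "at least 2")
})

test_that("the interval brackets the estimate and widens with the level", {
  set.seed(31)
  for (i in 1:20) {
    pre <- rnorm(10, 50, 10)
    post <- pre + rnorm(10, -2, 5)
    cs90 <- mean_change_ci(pre, post, level = 0.90)
    cs99 <- mean_change_ci(pre, post, level = 0.99)
    expect_lte(cs90$ci_low, cs90$mean_change)
    expect_gte(cs90$ci_high, cs90$mean_change)
    expect_lt(cs99$ci_low, cs90$ci_low)
    expect_gt(cs99$ci_high, cs90$ci_high)
  }
})

test_that("chi-square comparison matches the first-principles Pearson formula", {
  # observed gender split rounds to the reported p = .02
  gender <- default_observed_counts()$gender
  res <- compare_groups_categorical(gender)
  expect_equal(round(res$p_value, 2), 0.02)

  expect_equal(compare_groups_categorical(matrix(c(10, 0, 0, 10), 2))$statistic,
               20)
  expect_lt(compare_groups_categorical(matrix(c(10, 0, 0, 10), 2))$p_value,
            0.001)
  same <- matrix(c(7, 13, 7, 13), 2)
  expect_equal(compare_groups_categorical(same)$statistic, 0)
  expect_equal(compare_groups_categorical(same)$p_value, 1)

  # brute force over random 2x2 tables with margins <= 20
  set.seed(55)
  for (i in 1:50) {
    tab <- matrix(sample(1:10, 4, replace = TRUE), 2)
    got <- compare_groups_categorical(tab)
    want <- oracle_chisq(tab)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }

  expect_error(compare_groups_categorical(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(compare_groups_categorical(matrix(c(1.5, 2, 3, 4), 2)),
               "nonnegative integers")
})

test_that("continuous comparisons: exact Mann-Whitney, identical samples, power", {
  # complete separation of {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  mw <- compare_groups_continuous(c(1, 2, 3), c(4, 5, 6),
                                  method = "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)

  x <- c(2, 4, 6, 8)
  expect_equal(compare_groups_continuous(x, x, method = "t")$p_value, 1)
  expect_equal(compare_groups_continuous(x, x, method = "mann_whitney")$p_value,
               1)

  set.seed(13)
  a <- rnorm(1000); b <- rnorm(1000, 1)
  expect_lt(compare_groups_continuous(a, b, method = "auto")$p_value, 0.001)

  # normality gate: heavy ties push auto to the rank test
  skewed <- rep(c(0, 0, 0, 10), 25)
  res <- compare_groups_continuous(skewed, skewed + 1, method = "auto")
  expect_equal(res$method, "mann_whitney")
})

test_that("worsening classification uses a strict threshold on the decline", {
  expect_equal(classify_transition(50, 50, 0), "stable_or_improved")
  expect_equal(classify_transition(50, 40, 5), "worsened")
  # boundary: a drop equal to the threshold is not worsening
  expect_equal(classify_transition(50, 45, 5), "stable_or_improved")
  expect_equal(classify_transition(50, 55, 0), "stable_or_improved")
  expect_equal(classify_transition(50, 45, 0), "worsened")
  expect_true(is.na(classify_transition(50, NA, 0)))
  expect_error(classify_transition(50, 40, -1), ">= 0")
})

test_that("transition probabilities are complementary counts over the arm", {
  coh <- bernoulli_cohort(10, 0.3, seed = 1)
  coh$patients$barthel_1 <- c(rep(45, 3), rep(50, 7))  # exactly 3 worsened
  tr <- estimate_transition_probs(coh, "intervention")
  expect_equal(tr$incidence, 0.3)
  expect_equal(tr$recovery, 0.7)
  expect_equal(tr$incidence + tr$recovery, 1)
  expect_equal(tr$n, 10)

  none <- bernoulli_cohort(8, 0, seed = 2)
  tr0 <- estimate_transition_probs(none, "intervention")
  expect_equal(tr0$incidence, 0)
  expect_equal(tr0$recovery, 1)

  expect_error(estimate_transition_probs(none, "comparator"), "empty arm")

  # missing follow-up scores are excluded and counted
  miss <- bernoulli_cohort(10, 0.5, seed = 3)
  miss$patients$barthel_1[1:2] <- NA
  trm <- estimate_transition_probs(miss, "intervention")
  expect_equal(trm$n_excluded, 2)
  expect_equal(trm$n, 8)
})

test_that("worsening fractions are recovered within 3 binomial SE at n = 5000", {
  for (p in c(0.1, 0.34, 0.36, 0.9)) {
    coh <- bernoulli_cohort(5000, p, seed = round(1000 * p))
    est <- estimate_transition_probs(coh, "intervention")$incidence
    expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / 5000))
  }
})

test_that("the optional rate-based annualization lifts short-follow-up fractions", {
  coh <- bernoulli_cohort(1000, 0.34, seed = 4)
  p_obs <- estimate_transition_probs(coh, "intervention")$incidence
  p_ann <- estimate_transition_probs(coh, "intervention",
                                     annualize = TRUE)$incidence
  expect_equal(p_ann, 1 - (1 - p_obs)^(12 / 8), tolerance = 1e-12)
  expect_gt(p_ann, p_obs)
})

test_that("Barthel-utility mapping clips affine values and passes direct ones", {
  expect_equal(map_barthel_to_utility(100), 1)
  expect_equal(map_barthel_to_utility(0), 0)
  expect_equal(map_barthel_to_utility(45), 0.45)
  # clipping
  expect_equal(map_barthel_to_utility(90, utility_map(a = 0.5, b = 0.01)), 1)
  dm <- utility_map("direct", direct = c(baseline = 0.56, deteriorated = 0.30))
  expect_equal(map_barthel_to_utility("baseline", dm), 0.56)
  expect_equal(map_barthel_to_utility("deteriorated", dm), 0.30)
  expect_error(map_barthel_to_utility(120), "out of \\[0,100\\]")
  expect_error(map_barthel_to_utility("limbo", dm), "unknown state")
})

test_that("the effectiveness report covers every arm-instrument pair", {
  coh <- generate_cohort(tiny_cohort_config(seed = 21))
  rep <- effectiveness_report(coh)
  expect_equal(nrow(rep), 6)
  expect_setequal(rep$instrument, c("barthel", "iadl", "gds"))
  expect_true(all(rep$ci_low <= rep$mean_change & rep$mean_change <= rep$ci_high))
})
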