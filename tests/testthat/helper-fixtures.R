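# life table with the same qx at every age (both sexes)
constant_life_table <- function(qx, min_age = 20, max_age = 120) {
  ages <- min_age:max_age
  life_table(age = rep(ages, 2), sex = rep(c("F", "M"), each = length(ages)),
             qx = rep(qx, 2 * length(ages)))
}

# a random but valid parameter set for the Markov engine
random_markov_case <- function() {
  lt <- life_table(age = rep(60:110, 2),
                   sex = rep(c("F", "M"), each = 51),
                   qx = c(sort(runif(51, 0, 0.5)), sort(runif(51, 0, 0.5))))
  arm <- markov_arm("random",
                    incidence = runif(1), recovery = runif(1),
                    utility_baseline = runif(1), utility_deteriorated = runif(1),
                    cost_baseline = runif(1, 0, 10000),
                    cost_deteriorated = runif(1, 0, 10000),
                    rr_baseline = runif(1, 0.5, 2),
                    rr_deteriorated = runif(1, 0.5, 2),
                    one_off_cost = runif(1, 0, 2000),
                    recurring_cost = runif(1, 0, 500))
  econ <- econ_config(discount_effects = runif(1, 0, 0.06),
                      discount_costs = runif(1, 0, 0.06),
                      horizon = sample(5:40, 1),
                      start_age = sample(60:90, 1),
                      sex_mix_female = runif(1),
                      start_state_baseline = runif(1))
  list(arm = arm, econ = econ, lt = lt)
}

# small cohort config used where only structure (not moments) matters
tiny_cohort_config <- function(n_int = 8, n_comp = 9, seed = 42) {
  cfg <- default_cohort_config(n_intervention = n_int, n_comparator = n_comp,
                               seed = seed)
  cfg
}

# synthetic single-arm cohort with a prescribed worsening probability
bernoulli_cohort <- function(n, p_worsen, seed) {
  set.seed(seed)
  worsened <- rbinom(n, 1, p_worsen)
  patients <- data.frame(
    id = sprintf("intervention_%05d", seq_len(n)),
    arm = "intervention", age = 80, sex = "F", followup_months = 8,
    barthel_0 = 50, barthel_1 = 50 - 5 * worsened,
    iadl_0 = 4, iadl_1 = 4, gds_0 = 5, gds_1 = 5, charlson = 2,
    stringsAsFactors = FALSE)
  structure(list(patients = patients,
                 contacts = data.frame(patient_id = character(0)),
                 admissions = data.frame(patient_id = character(0)),
                 config = NULL),
            class = "cohort")
}
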