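# Independent oracles, deliberately written as a different formulation than
# the package internals: the Markov oracle builds an explicit 3x3 transition
# matrix each cycle and multiplies row vectors; the chi-square oracle is the
# first-principles Pearson formula.

oracle_run_arm <- function(arm, econ, lt) {
  stopifnot(!econ$half_cycle_correction)
  ltd <- as.data.frame(lt)
  qx_of <- function(age, sex) {
    a <- min(max(age, min(ltd$age)), max(ltd$age))
    ltd$qx[ltd$sex == sex & ltd$age == a]
  }
  total_q <- 0
  total_c <- arm$one_off_cost
  total_dly <- 0
  for (sex in c("F", "M")) {
    w <- if (sex == "F") econ$sex_mix_female else 1 - econ$sex_mix_female
    if (w == 0) next
    state <- c(econ$start_state_baseline, 1 - econ$start_state_baseline, 0)
    for (t in seq_len(econ$horizon)) {
      qx <- qx_of(econ$start_age + t - 1, sex)
      pb <- 1 - (1 - qx)^arm$rr_baseline
      pd <- 1 - (1 - qx)^arm$rr_deteriorated
      P <- rbind(
        c((1 - pb) * (1 - arm$incidence), (1 - pb) * arm$incidence, pb),
        c((1 - pd) * arm$recovery, (1 - pd) * (1 - arm$recovery), pd),
        c(0, 0, 1))
      state <- as.vector(state %*% P)
      ve <- (1 + econ$discount_effects)^(-t)
      vc <- (1 + econ$discount_costs)^(-t)
      alive <- state[1] + state[2]
      total_q <- total_q +
        w * (state[1] * arm$utility_baseline +
             state[2] * arm$utility_deteriorated) * ve
      total_c <- total_c +
        w * (state[1] * arm$cost_baseline + state[2] * arm$cost_deteriorated +
             alive * arm$recurring_cost) * vc
      total_dly <- total_dly + w * alive * ve
    }
  }
  list(total_qalys = total_q, total_costs = total_c,
       total_disc_life_years = total_dly)
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# mean of a normal clipped to [lower, upper] (closed form); grid rounding of
# a smooth density adds no first-order bias, so this is the generator's
# expected score mean
clipped_normal_mean <- function(mu, sigma, lower, upper) {
  zl <- (lower - mu) / sigma
  zu <- (upper - mu) / sigma
  lo_term <- if (is.finite(lower)) lower * pnorm(zl) else 0
  hi_term <- if (is.finite(upper)) upper * pnorm(zu, lower.tail = FALSE) else 0
  lo_term + hi_term + mu * (pnorm(zu) - pnorm(zl)) +
    sigma * (dnorm(zl) - dnorm(zu))
}
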