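#' Markov arm parameterisation
#'
#' Full economic parameterisation of one study arm for the three-state Markov
#' cohort model (baseline disease stage, deteriorated disease stage, dead):
#' per-cycle transition probabilities, state utilities and annual state costs,
#' mortality relative risks applied to life-table mortality, and programme
#' costs (one-off at model entry, recurring per alive patient-year).
#'
#' @param name arm label, e.g. `"intervention"`.
#' @param incidence per-cycle probability of baseline -> deteriorated.
#' @param recovery per-cycle probability of deteriorated -> baseline.
#' @param utility_baseline,utility_deteriorated QALY weights in `[0, 1]`.
#' @param cost_baseline,cost_deteriorated annual state costs (euro/patient-year).
#' @param rr_baseline,rr_deteriorated mortality relative risks (> 0), applied
#'   on the hazard scale to the life-table death probability.
#' @param one_off_cost programme cost charged once, undiscounted, at entry.
#' @param recurring_cost programme cost per alive patient-year.
#' @return An object of class `markov_arm`.
#' @seealso [run_arm()], [default_model_inputs()]
#' @export
markov_arm <- function(name, incidence, recovery,
                       utility_baseline, utility_deteriorated,
                       cost_baseline, cost_deteriorated,
                       rr_baseline = 1.005, rr_deteriorated = 1.005,
                       one_off_cost = 0, recurring_cost = 0) {
  chk_prob <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(what, " must be a probability in [0,1]", call. = FALSE)
  }
  chk_prob(incidence, "incidence"); chk_prob(recovery, "recovery")
  chk_prob(utility_baseline, "utility_baseline")
  chk_prob(utility_deteriorated, "utility_deteriorated")
  for (rr in c(rr_baseline, rr_deteriorated))
    if (!is.numeric(rr) || rr <= 0) stop("relative risks must be > 0", call. = FALSE)
  for (co in c(cost_baseline, cost_deteriorated, one_off_cost, recurring_cost))
    if (!is.numeric(co) || is.na(co) || co < 0) stop("costs must be >= 0", call. = FALSE)
  structure(list(name = as.character(name),
                 incidence = incidence, recovery = recovery,
                 utility_baseline = utility_baseline,
                 utility_deteriorated = utility_deteriorated,
                 cost_baseline = cost_baseline,
                 cost_deteriorated = cost_deteriorated,
                 rr_baseline = rr_baseline, rr_deteriorated = rr_deteriorated,
                 one_off_cost = one_off_cost, recurring_cost = recurring_cost),
            class = "markov_arm")
}

#' @export
print.markov_arm <- function(x, ...) {
  cat("Markov arm '", x$name, "'\n", sep = "")
  cat(sprintf("  incidence %.3f, recovery %.3f; rr %.4g/%.4g\n",
              x$incidence, x$recovery, x$rr_baseline, x$rr_deteriorated))
  cat(sprintf("  utilities %.3f/%.3f; state costs %.2f/%.2f EUR/yr\n",
              x$utility_baseline, x$utility_deteriorated,
              x$cost_baseline, x$cost_deteriorated))
  cat(sprintf("  programme costs: one-off %.2f, recurring %.2f EUR\n",
              x$one_off_cost, x$recurring_cost))
  invisible(x)
}

#' Economic model configuration
#'
#' Shared settings of a cohort model run: discount rates for effects and
#' costs, the time horizon in annual cycles, the cohort entry profile
#' (start age, sex mix, initial state occupancy) and the reward-timing
#' convention. Cycle length is fixed at one year.
#'
#' @param discount_effects,discount_costs annual discount rates (>= 0);
#'   default 3% for both.
#' @param horizon number of annual cycles (default 40, a lifetime horizon for
#'   an older cohort).
#' @param start_age cohort entry age in years.
#' @param sex_mix_female fraction of the cohort that is female.
#' @param start_state_baseline initial occupancy of the baseline disease
#'   stage (remainder starts deteriorated); default 1.
#' @param half_cycle_correction if `TRUE`, cycle rewards use the mean of the
#'   start- and end-of-cycle occupancy instead of end-of-cycle occupancy.
#'   Off by default.
#' @return An object of class `econ_config`.
#' @export
econ_config <- function(discount_effects = 0.03, discount_costs = 0.03,
                        horizon = 40, start_age = 84, sex_mix_female = 0.65,
                        start_state_baseline = 1,
                        half_cycle_correction = FALSE) {
  if (discount_effects < 0 || discount_costs < 0)
    stop("discount rates must be >= 0", call. = FALSE)
  if (horizon < 1) stop("horizon must be >= 1 cycle", call. = FALSE)
  if (sex_mix_female < 0 || sex_mix_female > 1)
    stop("sex_mix_female must be in [0,1]", call. = FALSE)
  if (start_state_baseline < 0 || start_state_baseline > 1)
    stop("start_state_baseline must be in [0,1]", call. = FALSE)
  structure(list(discount_effects = discount_effects,
                 discount_costs = discount_costs,
                 horizon = as.integer(horizon), cycle_length = 1,
                 start_age = start_age, sex_mix_female = sex_mix_female,
                 start_state_baseline = start_state_baseline,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "econ_config")
}

#' Run one arm of the three-state Markov cohort model
#'
#' Simulates state occupancy (baseline disease stage, deteriorated disease
#' stage, dead) over the model horizon and accumulates discounted QALYs,
#' discounted costs and life-years.
#'
#' Within each annual cycle death competes first — with probability
#' `1 - (1 - qx)^rr` from the current age/sex life-table row — then survivors
#' move between disease stages with the arm's incidence and recovery
#' probabilities. Age advances one year per cycle; ages beyond the life table
#' clamp to its terminal row. Cycle-`t` rewards are the end-of-cycle
#' occupancy times the state utility and annual state cost (plus the
#' recurring programme cost on alive occupancy), discounted by
#' `(1 + rate)^-t`; with `half_cycle_correction` the mean of start- and
#' end-of-cycle occupancy is used instead. The one-off programme cost is
#' charged undiscounted at entry. Sexes are modelled separately on their own
#' life-table columns and mixed by `sex_mix_female`.
#'
#' @param arm a [markov_arm()].
#' @param econ an [econ_config()].
#' @param life_table a [life_table()] covering the start age.
#' @return An object of class `markov_trace`: per-cycle occupancy,
#'   discounted QALY/cost increments, life-years, and their totals.
#' @export
#' @examples
#' arm <- markov_arm("usual care", incidence = 0.36, recovery = 0.64,
#'                   utility_baseline = 0.45, utility_deteriorated = 0.33,
#'                   cost_baseline = 5198.62, cost_deteriorated = 5221.69)
#' tr <- run_arm(arm, econ_config(), gompertz_life_table())
#' tr$total_qalys
run_arm <- function(arm, econ, life_table) {
  stopifnot(inherits(arm, "markov_arm"), inherits(econ, "econ_config"),
            inherits(life_table, "life_table"))
  arm <- do.call(markov_arm, unclass(arm))  # re-validate mutated fields
  if (econ$start_age < attr(life_table, "min_age"))
    stop("life table does not cover start age ", econ$start_age, call. = FALSE)
  T <- econ$horizon
  mix <- c(F = econ$sex_mix_female, M = 1 - econ$sex_mix_female)
  min_age <- attr(life_table, "min_age")
  max_age <- attr(life_table, "max_age")
  ages <- econ$start_age + 0:(T - 1L)                # age during each cycle
  idx <- pmin(pmax(floor(ages), min_age), max_age) - min_age + 1L

  occ <- matrix(0, T + 1L, 3L,
                dimnames = list(NULL, c("baseline", "deteriorated", "dead")))
  for (s in names(mix)) {
    w <- mix[[s]]
    if (w == 0) next
    qx <- qx_vector(life_table, s)[idx]
    qb <- 1 - (1 - qx)^arm$rr_baseline
    qd <- 1 - (1 - qx)^arm$rr_deteriorated
    o <- matrix(0, T + 1L, 3L)
    o[1L, ] <- c(econ$start_state_baseline, 1 - econ$start_state_baseline, 0)
    for (t in seq_len(T)) {
      b <- o[t, 1L]; d <- o[t, 2L]
      bs <- b * (1 - qb[t]); ds <- d * (1 - qd[t])   # survivors of the cycle
      o[t + 1L, 1L] <- bs * (1 - arm$incidence) + ds * arm$recovery
      o[t + 1L, 2L] <- bs * arm$incidence + ds * (1 - arm$recovery)
      o[t + 1L, 3L] <- o[t, 3L] + b * qb[t] + d * qd[t]
    }
    occ <- occ + w * o
  }

  occ_r <- if (econ$half_cycle_correction)
    (occ[1:T, , drop = FALSE] + occ[2:(T + 1L), , drop = FALSE]) / 2
  else occ[2:(T + 1L), , drop = FALSE]
  ve <- (1 + econ$discount_effects)^-(1:T)
  vc <- (1 + econ$discount_costs)^-(1:T)
  alive <- occ_r[, 1L] + occ_r[, 2L]
  qaly_t <- (occ_r[, 1L] * arm$utility_baseline +
             occ_r[, 2L] * arm$utility_deteriorated) * ve
  cost_t <- (occ_r[, 1L] * arm$cost_baseline +
             occ_r[, 2L] * arm$cost_deteriorated +
             alive * arm$recurring_cost) * vc

  structure(list(arm = arm, econ = econ,
                 cycle = 0:T, occupancy = occ,
                 disc_qalys = qaly_t, disc_costs = cost_t,
                 life_years = alive, disc_life_years = alive * ve,
                 total_qalys = sum(qaly_t),
                 total_costs = arm$one_off_cost + sum(cost_t),
                 total_life_years = sum(alive),
                 total_disc_life_years = sum(alive * ve)),
            class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, digits = 4, ...) {
  cat("Markov trace, arm '", x$arm$name, "': ", x$econ$horizon,
      " annual cycles from age ", x$econ$start_age, "\n", sep = "")
  cat(sprintf("  discounted QALYs %.*f, discounted costs %.2f EUR, life-years %.*f\n",
              digits, x$total_qalys, x$total_costs, digits, x$total_life_years))
  cat(sprintf("  final occupancy: baseline %.4f, deteriorated %.4f, dead %.4f\n",
              x$occupancy[nrow(x$occupancy), 1],
              x$occupancy[nrow(x$occupancy), 2],
              x$occupancy[nrow(x$occupancy), 3]))
  invisible(x)
}

#' @export
as.data.frame.markov_trace <- function(x, ...) {
  T <- x$econ$horizon
  data.frame(cycle = 0:T,
             baseline = x$occupancy[, 1L],
             deteriorated = x$occupancy[, 2L],
             dead = x$occupancy[, 3L],
             disc_qalys = c(0, x$disc_qalys),
             disc_costs = c(x$arm$one_off_cost, x$disc_costs),
             life_years = c(0, x$life_years))
}

#' @export
plot.markov_trace <- function(x, ...) {
  graphics::matplot(x$cycle, x$occupancy, type = "l", lty = 1, lwd = 2,
                    col = c("forestgreen", "orange", "grey30"),
                    xlab = "Cycle (years)", ylab = "Occupancy",
                    main = paste0("State occupancy: ", x$arm$name), ...)
  graphics::legend("right", legend = colnames(x$occupancy), lty = 1, lwd = 2,
                   col = c("forestgreen", "orange", "grey30"), bty = "n")
  invisible(x)
}

#' Closed-form discounted life-years under constant survival
#'
#' Analytic value of the discounted life-years accumulated by the cohort
#' model when per-cycle survival is a constant `s` and rewards fall at the
#' end of each cycle: `sum_{t=1..T} (s v)^t = s v (1 - (s v)^T) / (1 - s v)`
#' with `v = 1/(1 + discount)`. Serves as an independent analytic benchmark
#' for [run_arm()] under a constant-hazard life table.
#'
#' @param survival per-cycle survival probability in `[0, 1]`.
#' @param discount annual discount rate (>= 0).
#' @param horizon number of cycles.
#' @return discounted life-years.
#' @export
#' @examples
#' closed_form_dly(0.9, 0.03, 40)
closed_form_dly <- function(survival, discount, horizon) {
  stopifnot(survival >= 0, survival <= 1, discount >= 0, horizon >= 1)
  sv <- survival / (1 + discount)
  if (abs(1 - sv) < 1e-14) return(as.numeric(horizon))  # s*v -> 1 limit
  sv * (1 - sv^horizon) / (1 - sv)
}
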