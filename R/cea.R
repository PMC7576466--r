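#' Net monetary benefit
#'
#' `wtp * delta_effect - delta_cost`: positive exactly when the incremental
#' cost-effectiveness ratio lies below the willingness-to-pay threshold.
#'
#' @param delta_cost incremental cost (euro).
#' @param delta_effect incremental effect (QALYs).
#' @param wtp willingness-to-pay threshold (euro/QALY, >= 0).
#' @return net monetary benefit in euro.
#' @export
#' @examples
#' nmb(4755, 0.731, 15000)
nmb <- function(delta_cost, delta_effect, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * delta_effect - delta_cost
}

#' Incremental analysis of two Markov traces
#'
#' Computes incremental discounted costs and QALYs between an intervention
#' and a comparator trace run under the same economic configuration, the
#' ICER (or its dominance class when a ratio is not meaningful) and the net
#' monetary benefit at a willingness-to-pay threshold.
#'
#' Dominance classes follow the usual cost-effectiveness plane quadrants:
#' `"dominant"` (more effect for no more cost), `"dominated"` (less effect
#' for no less cost), `"icer"` otherwise; with zero incremental effect the
#' ICER is undefined (`NA`) but the net monetary benefit is still reported.
#'
#' @param trace_int,trace_comp [markov_trace][run_arm()] objects for the
#'   intervention and comparator arm.
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @return An object of class `cea_result` with per-arm totals,
#'   `delta_cost`, `delta_effect`, `icer`, `dominance`, `nmb`, `wtp`.
#' @export
compare_arms <- function(trace_int, trace_comp, wtp = 15000) {
  stopifnot(inherits(trace_int, "markov_trace"), inherits(trace_comp, "markov_trace"))
  e_int <- trace_int$econ; e_comp <- trace_comp$econ
  same <- vapply(setdiff(names(e_int), NULL),
                 function(f) identical(e_int[[f]], e_comp[[f]]), logical(1))
  if (!all(same))
    stop("traces were run under different economic configurations (",
         paste(names(same)[!same], collapse = ", "), ")", call. = FALSE)
  dc <- trace_int$total_costs - trace_comp$total_costs
  de <- trace_int$total_qalys - trace_comp$total_qalys
  if (de == 0) {
    icer <- NA_real_
    dominance <- if (dc == 0) "equivalent" else if (dc < 0) "dominant" else "dominated"
  } else if (de > 0 && dc <= 0) {
    icer <- dc / de; dominance <- "dominant"
  } else if (de < 0 && dc >= 0) {
    icer <- dc / de; dominance <- "dominated"
  } else {
    icer <- dc / de; dominance <- "icer"
  }
  structure(list(arms = c(trace_int$arm$name, trace_comp$arm$name),
                 qalys = c(intervention = trace_int$total_qalys,
                           comparator = trace_comp$total_qalys),
                 costs = c(intervention = trace_int$total_costs,
                           comparator = trace_comp$total_costs),
                 delta_cost = dc, delta_effect = de,
                 icer = icer, dominance = dominance,
                 nmb = nmb(dc, de, wtp), wtp = wtp),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental cost-utility result (", x$arms[1], " vs ", x$arms[2], ")\n", sep = "")
  cat(sprintf("  discounted QALYs: %.3f vs %.3f (delta %.3f)\n",
              x$qalys[1], x$qalys[2], x$delta_effect))
  cat(sprintf("  discounted costs: %.2f vs %.2f EUR (delta %.2f)\n",
              x$costs[1], x$costs[2], x$delta_cost))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (zero incremental effect); class '", x$dominance, "'\n", sep = "")
  } else {
    cat(sprintf("  ICER: %.2f EUR/QALY (%s)\n", x$icer, x$dominance))
  }
  cat(sprintf("  NMB at WTP %.0f EUR/QALY: %.2f EUR\n", x$wtp, x$nmb))
  invisible(x)
}

#' Fit the two-arm Markov cohort cost-utility model
#'
#' The package's central entry point: runs the three-state Markov cohort
#' model for an intervention and a comparator arm on a shared economic
#' configuration and life table, and derives the incremental analysis
#' (delta cost, delta effect, ICER, net monetary benefit).
#'
#' The returned object supports `print()`, `summary()`, `coef()` (the
#' incremental quantities), `plot()` (cost-effectiveness plane) and
#' `simulate()` (probabilistic sensitivity draws, see [psa()]).
#'
#' @param intervention,comparator [markov_arm()] objects.
#' @param econ an [econ_config()].
#' @param life_table a [life_table()].
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @return An object of class `markov_cea`: the inputs, both traces and the
#'   [compare_arms()] result.
#' @export
#' @examples
#' m <- markov_cea(default_model_inputs()$intervention,
#'                 default_model_inputs()$comparator)
#' coef(m)
markov_cea <- function(intervention, comparator, econ = econ_config(),
                       life_table = default_life_table(), wtp = 15000) {
  stopifnot(inherits(intervention, "markov_arm"), inherits(comparator, "markov_arm"))
  trace_int <- run_arm(intervention, econ, life_table)
  trace_comp <- run_arm(comparator, econ, life_table)
  structure(list(intervention = intervention, comparator = comparator,
                 econ = econ, life_table = life_table, wtp = wtp,
                 trace_intervention = trace_int, trace_comparator = trace_comp,
                 result = compare_arms(trace_int, trace_comp, wtp)),
            class = "markov_cea")
}

#' @export
print.markov_cea <- function(x, ...) {
  cat("Three-state Markov cohort cost-utility model\n")
  cat(sprintf("  horizon %d years from age %g (%.0f%% female); discounting %g%%/%g%% (effects/costs)\n",
              x$econ$horizon, x$econ$start_age, 100 * x$econ$sex_mix_female,
              100 * x$econ$discount_effects, 100 * x$econ$discount_costs))
  print(x$result)
  invisible(x)
}

#' @export
summary.markov_cea <- function(object, ...) {
  res <- object$result
  out <- list(call_arms = res$arms, econ = object$econ,
              per_arm = data.frame(
                arm = res$arms,
                disc_qalys = as.numeric(res$qalys),
                disc_costs = as.numeric(res$costs),
                disc_life_years = c(object$trace_intervention$total_disc_life_years,
                                    object$trace_comparator$total_disc_life_years)),
              delta_cost = res$delta_cost, delta_effect = res$delta_effect,
              icer = res$icer, dominance = res$dominance,
              nmb = res$nmb, wtp = res$wtp)
  class(out) <- "summary.markov_cea"
  out
}

#' @export
print.summary.markov_cea <- function(x, ...) {
  cat("Three-state Markov cohort cost-utility model\n\nPer-arm discounted totals:\n")
  df <- x$per_arm
  df$disc_qalys <- round(df$disc_qalys, 3)
  df$disc_costs <- round(df$disc_costs, 2)
  df$disc_life_years <- round(df$disc_life_years, 3)
  print(df, row.names = FALSE)
  cat(sprintf("\nIncremental cost: %.2f EUR\nIncremental effect: %.3f QALYs\n",
              x$delta_cost, x$delta_effect))
  if (is.na(x$icer)) cat("ICER: undefined\n")
  else cat(sprintf("ICER: %.2f EUR/QALY (%s)\n", x$icer, x$dominance))
  cat(sprintf("NMB at WTP %.0f: %.2f EUR\n", x$wtp, x$nmb))
  invisible(x)
}

#' @export
coef.markov_cea <- function(object, ...) {
  res <- object$result
  c(delta_cost = res$delta_cost, delta_effect = res$delta_effect,
    icer = res$icer, nmb = res$nmb)
}

#' @export
plot.markov_cea <- function(x, ...) {
  plot(ce_plane(list(x$result), wtp = x$wtp), ...)
  invisible(x)
}

#' @export
simulate.markov_cea <- function(object, nsim = 1000, seed = NULL, ...) {
  psa(object, n_draws = nsim, seed = seed, ...)
}
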