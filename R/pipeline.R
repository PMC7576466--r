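#' Full-run configuration
#'
#' Bundles every stage's settings into one reproducible run description.
#' Three modes are supported: `"reference"` runs the Markov model and
#' sensitivity sweeps directly on the packaged (or supplied) model inputs —
#' the pass-through path used when no patient-level data exist;
#' `"synthetic"` first generates a cohort, computes effectiveness and
#' costing, derives the model inputs from them and then runs the model;
#' `"patient_data"` does the same from cohort tables on disk.
#'
#' @param mode `"reference"`, `"synthetic"` or `"patient_data"`.
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param cohort_dir directory of cohort tables (patient_data mode).
#' @param costs a [unit_costs()].
#' @param program a [program_costs()].
#' @param model list with [markov_arm()] elements `intervention` and
#'   `comparator` (reference mode); default [default_model_inputs()].
#' @param econ an [econ_config()].
#' @param sweeps list of [sweep_spec()]s to run after the base case.
#' @param perspective costing perspective for derived or packaged inputs.
#' @param life_table_path optional life-table file; `NULL` uses the
#'   packaged synthetic Gompertz table.
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @param seed global seed for every random stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("reference", "synthetic", "patient_data"),
                       cohort = default_cohort_config(),
                       cohort_dir = NULL,
                       costs = unit_costs(), program = program_costs(),
                       model = default_model_inputs(perspective),
                       econ = econ_config(),
                       sweeps = default_sweeps(wtp),
                       perspective = c("healthcare", "societal"),
                       life_table_path = NULL, wtp = 15000, seed = 1L) {
  mode <- match.arg(mode)
  perspective <- match.arg(perspective)
  if (mode == "patient_data" && is.null(cohort_dir))
    stop("patient_data mode needs cohort_dir", call. = FALSE)
  if (!is.null(life_table_path) && !file.exists(life_table_path))
    stop("life table file not found: ", life_table_path, call. = FALSE)
  structure(list(mode = mode, cohort = cohort, cohort_dir = cohort_dir,
                 costs = costs, program = program, model = model, econ = econ,
                 sweeps = sweeps, perspective = perspective,
                 life_table_path = life_table_path, wtp = wtp,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Default sensitivity sweeps
#'
#' The two first-class sweep families: the intervention arm's
#' baseline-stage utility, and the per-state health-care costs of both arms
#' jointly, each over +/-5% in 0.5% steps.
#'
#' @param wtp willingness-to-pay threshold.
#' @return named list of [sweep_spec()]s.
#' @export
default_sweeps <- function(wtp = 15000) {
  list(utility = sweep_spec("intervention.utility_baseline", wtp = wtp),
       cost = sweep_spec(c("intervention.cost_baseline",
                           "intervention.cost_deteriorated",
                           "comparator.cost_baseline",
                           "comparator.cost_deteriorated"), wtp = wtp))
}

#' Derive Markov model inputs from a patient-level cohort
#'
#' Turns a cohort into the two [markov_arm()] parameterisations: incidence
#' and recovery from the disease-stage classification, per-state utilities
#' from the mean follow-up Barthel score of each stratum through the
#' utility mapping, per-state costs from [state_conditional_costs()] under
#' the chosen perspective, and programme costs on the intervention arm.
#' An empty stratum falls back to the arm-wide mean (flagged by the
#' costing report).
#'
#' @param cohort a `cohort` object.
#' @param costs a [unit_costs()].
#' @param program a [program_costs()].
#' @param perspective `"healthcare"` or `"societal"`.
#' @param map a [utility_map()] (default affine `u = Barthel/100`).
#' @param threshold worsening threshold in Barthel points.
#' @return list with `intervention` and `comparator` [markov_arm()]s.
#' @export
derive_model_inputs <- function(cohort, costs = unit_costs(),
                                program = program_costs(),
                                perspective = c("healthcare", "societal"),
                                map = utility_map(), threshold = 0) {
  perspective <- match.arg(perspective)
  pc <- patient_perspective_costs(cohort, costs, perspective)
  arms <- lapply(c(intervention = "intervention", comparator = "comparator"),
    function(arm) {
      tr <- estimate_transition_probs(cohort, arm, "barthel", threshold)
      sel <- pc$arm == arm
      p <- cohort$patients[match(pc$patient_id[sel], cohort$patients$id), ]
      cls <- classify_transition(p$barthel_0, p$barthel_1, threshold)
      scc <- state_conditional_costs(pc[sel, , drop = FALSE], cls)
      fallback_cost <- mean(pc$total[sel])
      cost_of <- function(st) {
        v <- scc$mean_cost[scc$state == st]
        if (is.na(v)) fallback_cost else v
      }
      util_of <- function(st) {
        want <- if (st == "baseline") "stable_or_improved" else "worsened"
        sc <- p$barthel_1[!is.na(cls) & cls == want]
        if (!length(sc)) sc <- p$barthel_1[!is.na(p$barthel_1)]
        if (map$mode == "affine") map_barthel_to_utility(mean(sc), map)
        else map_barthel_to_utility(st, map)
      }
      prog <- arm_program_costs(program, arm)
      markov_arm(arm, incidence = tr$incidence, recovery = tr$recovery,
                 utility_baseline = util_of("baseline"),
                 utility_deteriorated = util_of("deteriorated"),
                 cost_baseline = cost_of("baseline"),
                 cost_deteriorated = cost_of("deteriorated"),
                 one_off_cost = prog[["one_off"]],
                 recurring_cost = prog[["recurring"]])
    })
  arms
}

#' Run the full analysis pipeline
#'
#' Executes the configured mode's stages in order and writes every artifact
#' to `out_dir` as delimited text plus a machine-readable JSON summary:
#' cohort tables (synthetic mode), the effectiveness report, the cost
#' report, per-cycle Markov traces, the incremental result, sweep grids and
#' `summary.json`. The run configuration is echoed to `run_config.json`, so
#' a run can be re-created from its output directory alone (see
#' [read_run_config()]). Every random stage is seeded from the global seed;
#' reruns of the same configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the fitted [markov_cea()] model, the
#'   sweep results, the summary list and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtab <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                             sep = "\t", quote = FALSE,
                                             row.names = FALSE)
  lt <- if (is.null(config$life_table_path)) default_life_table()
        else read_life_table(config$life_table_path)

  stage <- "configuration"
  summary <- list(mode = config$mode, seed = config$seed,
                  perspective = config$perspective)
  result <- tryCatch({
    if (config$mode == "reference") {
      model_inputs <- config$model
    } else {
      stage <- "cohort"
      cohort <- if (config$mode == "synthetic") {
        cfg <- config$cohort
        cfg$seed <- config$seed
        generate_cohort(cfg)
      } else read_cohort(config$cohort_dir)
      if (config$mode == "synthetic") write_cohort(cohort, out_dir)
      stage <- "effectiveness"
      eff <- effectiveness_report(cohort)
      wtab(eff, "effectiveness_report.tsv")
      stage <- "costing"
      wtab(cost_report(cohort, config$costs), "cost_report.tsv")
      stage <- "model derivation"
      model_inputs <- derive_model_inputs(cohort, config$costs,
                                          config$program, config$perspective)
    }
    stage <- "markov model"
    fit <- markov_cea(model_inputs$intervention, model_inputs$comparator,
                      config$econ, lt, wtp = config$wtp)
    wtab(as.data.frame(fit$trace_intervention), "trace_intervention.tsv")
    wtab(as.data.frame(fit$trace_comparator), "trace_comparator.tsv")
    stage <- "sensitivity"
    sweeps <- lapply(config$sweeps, function(sp) one_way_sweep(fit, sp))
    for (nm in names(sweeps))
      wtab(sweeps[[nm]]$grid, paste0("sweep_", nm, ".tsv"))
    wtab(ce_plane(list(fit$result), config$wtp)$points, "ce_plane.tsv")
    list(fit = fit, sweeps = sweeps)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  res <- result$fit$result
  summary <- c(summary, list(
    qalys_intervention = unname(res$qalys["intervention"]),
    qalys_comparator = unname(res$qalys["comparator"]),
    costs_intervention = unname(res$costs["intervention"]),
    costs_comparator = unname(res$costs["comparator"]),
    delta_cost = res$delta_cost, delta_effect = res$delta_effect,
    icer = res$icer, dominance = res$dominance,
    nmb = res$nmb, wtp = res$wtp,
    sweep_max_icer = lapply(result$sweeps, `[[`, "max_icer"),
    sweep_all_below_wtp = lapply(result$sweeps, `[[`, "all_below_wtp")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(out_dir, "run_config.json"))
  invisible(list(fit = result$fit, sweeps = result$sweeps, summary = summary,
                 out_dir = out_dir))
}

#' Write / read a run configuration
#'
#' JSON serialisation of a [run_config()], sufficient to re-create a run
#' from its output directory.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a rebuilt `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)  # keep names in JSON
    else x
  }
  payload <- list(
    mode = config$mode, seed = config$seed, wtp = config$wtp,
    perspective = config$perspective,
    life_table_path = config$life_table_path,
    cohort_dir = config$cohort_dir,
    cohort = strip(config$cohort), costs = strip(config$costs),
    program = strip(config$program), econ = strip(config$econ),
    model = strip(config$model),
    sweeps = lapply(config$sweeps, strip))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nz <- function(v) if (length(v)) v else NULL   # {} round-trips as NULL
  rebuild_arm_cfg <- function(a) {
    a$comorbidity_prevalence <- unlist(a$comorbidity_prevalence)
    a$professional_mix <- unlist(a$professional_mix)
    a$setting_mix <- unlist(a$setting_mix)
    a$score_baseline <- lapply(a$score_baseline, unlist)
    a$score_change <- lapply(a$score_change, unlist)
    do.call(arm_cohort_config, a)
  }
  cohort <- cohort_config(rebuild_arm_cfg(x$cohort$intervention),
                          rebuild_arm_cfg(x$cohort$comparator),
                          followup_months = x$cohort$followup_months,
                          seed = x$cohort$seed)
  costs <- do.call(unit_costs, within(x$costs, {
    contact_durations <- unlist(contact_durations)
  }))
  arm_from <- function(a) do.call(markov_arm, a)
  econ <- do.call(econ_config, x$econ[setdiff(names(x$econ), "cycle_length")])
  run_config(mode = x$mode, cohort = cohort,
             cohort_dir = nz(x$cohort_dir),
             costs = costs,
             program = program_costs(x$program$one_off, x$program$recurring),
             model = list(intervention = arm_from(x$model$intervention),
                          comparator = arm_from(x$model$comparator)),
             econ = econ,
             sweeps = lapply(x$sweeps, function(s)
               sweep_spec(s$parameter, unlist(s$relative_range),
                          s$n_points, s$wtp)),
             perspective = x$perspective,
             life_table_path = nz(x$life_table_path),
             wtp = x$wtp, seed = x$seed)
}
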