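#' Paired mean change with confidence interval
#'
#' Mean follow-up change (`post - pre`) with a paired-t confidence interval
#' and two-sided p-value. When the differences have zero variance the CI
#' collapses to the point estimate and the p-value is 1 for a zero mean
#' (no evidence of change) and 0 for a nonzero constant change (the t
#' statistic diverges).
#'
#' @param pre,post equal-length paired score vectors, `n >= 2`.
#' @param level confidence level (default 0.95).
#' @return list of class `change_summary`: `n`, `mean_change`, `ci_low`,
#'   `ci_high`, `p_value`, `level`.
#' @export
#' @examples
#' mean_change_ci(c(10, 20, 30), c(11, 22, 33))
mean_change_ci <- function(pre, post, level = 0.95) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  keep <- stats::complete.cases(pre, post)
  d <- post[keep] - pre[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  m <- mean(d)
  if (stats::sd(d) == 0) {
    out <- list(n = n, mean_change = m, ci_low = m, ci_high = m,
                p_value = if (m == 0) 1 else 0, level = level)
  } else {
    tt <- stats::t.test(d, conf.level = level)
    out <- list(n = n, mean_change = m,
                ci_low = unname(tt$conf.int[1]), ci_high = unname(tt$conf.int[2]),
                p_value = tt$p.value, level = level)
  }
  structure(out, class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("mean change %.3f (%.0f%% CI %.3f to %.3f; p = %.3g; n = %d)\n",
              x$mean_change, 100 * x$level, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Chi-square comparison of categorical distributions
#'
#' Pearson chi-square test between groups on a 2-by-k (or r-by-k) table of
#' counts, without continuity correction by default. Expected counts are
#' returned as a diagnostic (the chi-square approximation weakens when they
#' fall below 5).
#'
#' @param counts matrix of nonnegative integer counts with at least two
#'   nonzero rows and columns.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return list: `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' compare_groups_categorical(default_observed_counts()$gender)
compare_groups_categorical <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Two-group comparison of a continuous outcome
#'
#' Welch t test, Mann-Whitney U test, or an automatic choice gated on
#' normality: with `method = "auto"` both samples are screened with a
#' Kolmogorov-Smirnov test against a normal with the sample moments at
#' alpha = 0.05; the t test is used only when neither sample rejects
#' normality. All p-values are two-sided.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param method `"auto"`, `"t"` or `"mann_whitney"`.
#' @return list: `statistic`, `p_value`, `method` (the test actually used).
#' @export
#' @examples
#' compare_groups_continuous(rnorm(20), rnorm(20, 1), method = "t")
compare_groups_continuous <- function(a, b, method = c("auto", "t", "mann_whitney")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (method == "auto") {
    normal <- function(x) {
      if (stats::sd(x) == 0) return(FALSE)
      p <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$p.value
      p >= 0.05
    }
    method <- if (normal(a) && normal(b)) "t" else "mann_whitney"
  }
  if (method == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, method = "t"))
    tt <- stats::t.test(a, b)
    list(statistic = unname(tt$statistic), p_value = tt$p.value, method = "t")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "mann_whitney")
  }
}

#' Classify patients as worsened or stable/improved
#'
#' Disease-stage classification behind the Markov transition probabilities:
#' a patient has worsened when the follow-up score drops strictly more than
#' the worsening threshold, i.e. `final - baseline < -threshold`. With the
#' default threshold 0 any score decline counts as worsening. Missing
#' follow-up scores yield `NA` and are excluded (and counted) downstream.
#'
#' @param baseline,final score vectors at enrolment and follow-up.
#' @param threshold nonnegative worsening threshold in score units.
#' @return character vector, `"worsened"` or `"stable_or_improved"` (or `NA`).
#' @export
#' @examples
#' classify_transition(c(50, 50, 50), c(40, 45, 50), threshold = 5)
classify_transition <- function(baseline, final, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  ifelse(is.na(baseline) | is.na(final), NA_character_,
         ifelse(final - baseline < -threshold, "worsened", "stable_or_improved"))
}

#' Estimate Markov transition probabilities from a cohort arm
#'
#' Incidence (the worsened fraction) with recovery estimated as its
#' complement — the two per-cycle transition probabilities of the
#' three-state model. The observed follow-up fraction is used directly as
#' the per-cycle (annual) probability by default; set `annualize = TRUE`
#' for a constant-rate conversion `1 - (1 - p)^(12/m)` over an `m`-month
#' follow-up.
#'
#' @param cohort a [generate_cohort()]/[read_cohort()] object.
#' @param arm `"intervention"` or `"comparator"`.
#' @param instrument score used for classification (default `"barthel"`).
#' @param threshold worsening threshold, see [classify_transition()].
#' @param annualize convert the observed fraction to an annual probability.
#' @return list of class `transition_estimates`: `incidence`, `recovery`,
#'   `n`, `n_excluded`, `threshold`.
#' @export
estimate_transition_probs <- function(cohort, arm, instrument = "barthel",
                                      threshold = 0, annualize = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients[cohort$patients$arm == arm, ]
  if (!nrow(p)) stop("empty arm: ", arm, call. = FALSE)
  cls <- classify_transition(p[[paste0(instrument, "_0")]],
                             p[[paste0(instrument, "_1")]], threshold)
  n_excluded <- sum(is.na(cls))
  cls <- cls[!is.na(cls)]
  if (!length(cls))
    stop("no patients with both timepoints in arm ", arm, call. = FALSE)
  inc <- mean(cls == "worsened")
  if (annualize) {
    m <- p$followup_months[1]
    inc <- 1 - (1 - inc)^(12 / m)
  }
  structure(list(incidence = inc, recovery = 1 - inc, n = length(cls),
                 n_excluded = n_excluded, threshold = threshold),
            class = "transition_estimates")
}

#' @export
print.transition_estimates <- function(x, ...) {
  cat(sprintf("transition estimates: incidence %.3f, recovery %.3f (n = %d, %d excluded)\n",
              x$incidence, x$recovery, x$n, x$n_excluded))
  invisible(x)
}

#' Barthel-to-utility mapping
#'
#' Pluggable proxy mapping from the Barthel index to a QALY utility weight.
#' `affine` mode applies `u = a + b * score` clipped to `[0, 1]` (default
#' `u = score/100`); `direct` mode returns pre-specified per-state utilities
#' unchanged, which is how externally published utility values enter the
#' model.
#'
#' @param mode `"affine"` or `"direct"`.
#' @param a,b affine intercept and slope.
#' @param direct named utilities (`baseline`, `deteriorated`) for direct mode.
#' @return object of class `utility_map`.
#' @export
utility_map <- function(mode = c("affine", "direct"), a = 0, b = 0.01,
                        direct = c(baseline = NA_real_, deteriorated = NA_real_)) {
  mode <- match.arg(mode)
  if (mode == "direct" && any(!is.na(direct) & (direct < 0 | direct > 1)))
    stop("direct utilities must be in [0,1]", call. = FALSE)
  structure(list(mode = mode, a = a, b = b, direct = direct),
            class = "utility_map")
}

#' @param score Barthel score(s) in `[0, 100]` (affine mode) or a state name
#'   (`"baseline"`/`"deteriorated"`, direct mode).
#' @param map a [utility_map()].
#' @rdname utility_map
#' @export
#' @examples
#' map_barthel_to_utility(100, utility_map())
#' map_barthel_to_utility("baseline",
#'   utility_map("direct", direct = c(baseline = 0.56, deteriorated = 0.30)))
map_barthel_to_utility <- function(score, map = utility_map()) {
  stopifnot(inherits(map, "utility_map"))
  if (map$mode == "affine") {
    if (!is.numeric(score) || any(score < 0 | score > 100, na.rm = TRUE))
      stop("Barthel score out of [0,100]", call. = FALSE)
    pmin(pmax(map$a + map$b * score, 0), 1)
  } else {
    if (!all(score %in% names(map$direct)))
      stop("unknown state for direct utility mode: ",
           paste(setdiff(score, names(map$direct)), collapse = ", "),
           call. = FALSE)
    unname(map$direct[score])
  }
}

#' Clinical-effectiveness report for a cohort
#'
#' One row per arm and instrument with the paired mean change, confidence
#' interval and p-value.
#'
#' @param cohort a `cohort` object.
#' @param level confidence level.
#' @return data.frame with columns `arm`, `instrument`, `n`, `mean_change`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
effectiveness_report <- function(cohort, level = 0.95) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  for (arm in unique(cohort$patients$arm)) {
    p <- cohort$patients[cohort$patients$arm == arm, ]
    for (ins in c("barthel", "iadl", "gds")) {
      cs <- mean_change_ci(p[[paste0(ins, "_0")]], p[[paste0(ins, "_1")]], level)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, instrument = ins, n = cs$n, mean_change = cs$mean_change,
        ci_low = cs$ci_low, ci_high = cs$ci_high, p_value = cs$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
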