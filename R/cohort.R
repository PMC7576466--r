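#' Per-arm cohort generation settings
#'
#' Parameters of the synthetic patient generator for one study arm:
#' demographics, comorbidity prevalences, baseline functional scores and
#' their follow-up changes, contact and hospitalization behaviour.
#'
#' Score parameters are supplied per instrument as `c(mean, sd)` for
#' `barthel` (0-100 in steps of 5), `iadl` (0-8) and `gds` (0-15). The
#' contact mix is given as marginal probabilities over professional type,
#' contact setting and planned/unplanned anticipation; the joint mix is
#' their product (only marginal profiles are observed in practice).
#'
#' @param n number of patients in the arm (>= 1).
#' @param age_mean,age_sd age distribution in years (Gaussian; ages are
#'   floored at 65, the programme's eligibility age).
#' @param female_fraction probability that a patient is female.
#' @param comorbidity_prevalence named probabilities over the conditions of
#'   [charlson_weights()].
#' @param score_baseline,score_change named lists with elements `barthel`,
#'   `iadl`, `gds`, each `c(mean, sd)`.
#' @param contact_rate expected professional contacts per patient-year.
#' @param professional_mix probabilities over `gp`, `specialist`, `nurse`,
#'   `other_health`, `social_worker`, `volunteer` (renormalised).
#' @param setting_mix probabilities over `out_of_home`, `home_visit`,
#'   `telephone`, `writing`, `other` (renormalised).
#' @param planned_prob probability that a contact is planned.
#' @param admission_prob probability that a patient is hospitalized at all
#'   during follow-up.
#' @param mean_admissions expected admissions per patient (all patients);
#'   must be >= `admission_prob`.
#' @param los_mean,los_sd length of stay per admission in days (lognormal by
#'   moment matching: hospital stays are non-negative and right-skewed).
#' @param planned_admission_prob probability an admission is planned.
#' @param readmission_prob probability an admission is a <=30-day readmission.
#' @return An object of class `arm_cohort_config`.
#' @seealso [cohort_config()], [generate_cohort()]
#' @export
arm_cohort_config <- function(n, age_mean, age_sd, female_fraction,
                              comorbidity_prevalence,
                              score_baseline, score_change,
                              contact_rate, professional_mix, setting_mix,
                              planned_prob, admission_prob, mean_admissions,
                              los_mean, los_sd,
                              planned_admission_prob = 0.3,
                              readmission_prob = 0.2) {
  fail <- function(field, why) stop("invalid arm_cohort_config field '", field,
                                    "': ", why, call. = FALSE)
  if (!is.numeric(n) || n < 1) fail("n", "must be >= 1")
  if (age_sd < 0) fail("age_sd", "sd must be >= 0")
  for (p in c("female_fraction", "planned_prob", "admission_prob",
              "planned_admission_prob", "readmission_prob")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1) fail(p, "must be a probability in [0,1]")
  }
  if (any(comorbidity_prevalence < 0 | comorbidity_prevalence > 1))
    fail("comorbidity_prevalence", "all prevalences must be in [0,1]")
  unknown <- setdiff(names(comorbidity_prevalence), names(charlson_weights()))
  if (length(unknown))
    fail("comorbidity_prevalence", paste("unknown condition(s):",
                                         paste(unknown, collapse = ", ")))
  for (blk_name in c("score_baseline", "score_change")) {
    blk <- get(blk_name)
    if (!all(c("barthel", "iadl", "gds") %in% names(blk)))
      fail(blk_name, "needs elements barthel, iadl, gds")
    if (any(vapply(blk, function(x) length(x) != 2 || x[2] < 0, logical(1))))
      fail(blk_name, "each instrument needs c(mean, sd) with sd >= 0")
  }
  if (contact_rate < 0) fail("contact_rate", "must be >= 0")
  if (any(professional_mix < 0) || sum(professional_mix) <= 0)
    fail("professional_mix", "probabilities must be >= 0 and sum > 0")
  if (any(setting_mix < 0) || sum(setting_mix) <= 0)
    fail("setting_mix", "probabilities must be >= 0 and sum > 0")
  if (mean_admissions < admission_prob)
    fail("mean_admissions", "must be >= admission_prob")
  if (los_mean < 0 || los_sd < 0) fail("los_mean/los_sd", "must be >= 0")
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 comorbidity_prevalence = comorbidity_prevalence,
                 score_baseline = score_baseline, score_change = score_change,
                 contact_rate = contact_rate,
                 professional_mix = professional_mix / sum(professional_mix),
                 setting_mix = setting_mix / sum(setting_mix),
                 planned_prob = planned_prob,
                 admission_prob = admission_prob,
                 mean_admissions = mean_admissions,
                 los_mean = los_mean, los_sd = los_sd,
                 planned_admission_prob = planned_admission_prob,
                 readmission_prob = readmission_prob),
            class = "arm_cohort_config")
}

#' Two-arm cohort generation settings
#'
#' @param intervention,comparator [arm_cohort_config()] objects.
#' @param followup_months follow-up duration in months (> 0; default 8).
#' @param seed integer seed driving all randomness of [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(intervention, comparator, followup_months = 8,
                          seed = 1L) {
  if (!inherits(intervention, "arm_cohort_config"))
    stop("invalid cohort_config field 'intervention': not an arm_cohort_config",
         call. = FALSE)
  if (!inherits(comparator, "arm_cohort_config"))
    stop("invalid cohort_config field 'comparator': not an arm_cohort_config",
         call. = FALSE)
  if (!is.numeric(followup_months) || followup_months <= 0)
    stop("invalid cohort_config field 'followup_months': must be > 0",
         call. = FALSE)
  structure(list(intervention = intervention, comparator = comparator,
                 followup_months = followup_months, seed = as.integer(seed)),
            class = "cohort_config")
}

# instrument ranges and grid steps
score_grid <- function(instrument) {
  switch(instrument,
         barthel = list(lower = 0, upper = 100, step = 5),
         iadl = list(lower = 0, upper = 8, step = 1),
         gds = list(lower = 0, upper = 15, step = 1),
         stop("unknown instrument: ", instrument, call. = FALSE))
}

clip_to_grid <- function(x, lower, upper, step) {
  pmin(pmax(round(x / step) * step, lower), upper)
}

#' Sample baseline and follow-up scores for one instrument
#'
#' Draws a Gaussian baseline and a Gaussian follow-up change, then clips and
#' rounds both to the instrument's grid (Barthel to multiples of 5 in
#' [0, 100]; IADL to integers in [0, 8]; GDS to integers in [0, 15]). The
#' final score is `clip(grid(baseline + change))`, so ceiling and floor
#' effects are handled by construction.
#'
#' @param n number of patients.
#' @param baseline,change `c(mean, sd)` of the baseline score and its
#'   follow-up change.
#' @param instrument `"barthel"`, `"iadl"` or `"gds"`.
#' @return `data.frame(baseline, final)` with `n` rows, both on the
#'   instrument grid. Uses the current RNG stream.
#' @export
#' @examples
#' set.seed(1)
#' sample_score_trajectory(5, c(45, 27), c(-3, 10), "barthel")
sample_score_trajectory <- function(n, baseline, change, instrument) {
  g <- score_grid(instrument)
  b <- clip_to_grid(stats::rnorm(n, baseline[1], baseline[2]),
                    g$lower, g$upper, g$step)
  f <- clip_to_grid(b + stats::rnorm(n, change[1], change[2]),
                    g$lower, g$upper, g$step)
  data.frame(baseline = b, final = f)
}

#' Charlson comorbidity score
#'
#' Sum of the weights of the present comorbidities. Unknown flags are
#' rejected rather than silently scored zero.
#'
#' @param comorbidities character vector of condition flags.
#' @param weights named weight map; default [charlson_weights()].
#' @return non-negative integer score.
#' @export
#' @examples
#' charlson_score(c("myocardial_infarction", "congestive_heart_failure"))
charlson_score <- function(comorbidities, weights = charlson_weights()) {
  comorbidities <- unique(as.character(comorbidities))
  unknown <- setdiff(comorbidities, names(weights))
  if (length(unknown))
    stop("unknown comorbidity flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(weights[comorbidities])
}

lognormal_pars <- function(m, s) {
  # moment matching; degenerate sd -> point mass at m
  if (s <= 0 || m <= 0) return(list(meanlog = log(max(m, 1e-12)), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

generate_patient <- function(id, arm_name, cfg, followup_months) {
  female <- stats::runif(1) < cfg$female_fraction
  age <- max(65, round(stats::rnorm(1, cfg$age_mean, cfg$age_sd), 1))
  cm <- stats::runif(length(cfg$comorbidity_prevalence)) < cfg$comorbidity_prevalence
  names(cm) <- names(cfg$comorbidity_prevalence)
  scores <- lapply(c(barthel = "barthel", iadl = "iadl", gds = "gds"),
                   function(ins) sample_score_trajectory(
                     1, cfg$score_baseline[[ins]], cfg$score_change[[ins]], ins))

  n_contacts <- stats::rpois(1, cfg$contact_rate * followup_months / 12)
  contacts <- if (n_contacts > 0) {
    professional <- sample(names(cfg$professional_mix), n_contacts,
                           replace = TRUE, prob = cfg$professional_mix)
    setting <- sample(names(cfg$setting_mix), n_contacts,
                      replace = TRUE, prob = cfg$setting_mix)
    data.frame(patient_id = id, professional = professional, setting = setting,
               planned = stats::runif(n_contacts) < cfg$planned_prob,
               duration = unname(default_contact_durations()[setting]),
               stringsAsFactors = FALSE)
  } else NULL

  admissions <- NULL
  if (stats::runif(1) < cfg$admission_prob) {
    # 1 + Poisson so the unconditional mean equals mean_admissions
    n_adm <- 1L + stats::rpois(1, cfg$mean_admissions / cfg$admission_prob - 1)
    lp <- lognormal_pars(cfg$los_mean, cfg$los_sd)
    admissions <- data.frame(
      patient_id = id,
      planned = stats::runif(n_adm) < cfg$planned_admission_prob,
      bed_days = round(stats::rlnorm(n_adm, lp$meanlog, lp$sdlog), 1),
      readmission_within_30d = stats::runif(n_adm) < cfg$readmission_prob,
      stringsAsFactors = FALSE)
  }

  patient <- data.frame(id = id, arm = arm_name, age = age,
                        sex = if (female) "F" else "M",
                        followup_months = followup_months,
                        barthel_0 = scores$barthel$baseline,
                        barthel_1 = scores$barthel$final,
                        iadl_0 = scores$iadl$baseline,
                        iadl_1 = scores$iadl$final,
                        gds_0 = scores$gds$baseline,
                        gds_1 = scores$gds$final,
                        charlson = charlson_score(names(cm)[cm]),
                        stringsAsFactors = FALSE)
  for (nm in names(cm)) patient[[paste0("cm_", nm)]] <- unname(cm[nm])
  list(patient = patient, contacts = contacts, admissions = admissions)
}

#' Generate a synthetic two-arm cohort
#'
#' Simulates patient-level data with the statistical structure the economic
#' analysis assumes: Gaussian demographics and functional scores (clipped
#' and grid-rounded to each instrument's range), Bernoulli comorbidity
#' flags, Poisson professional contacts with a multinomial
#' professional/setting/planned mix, and lognormal hospital stays.
#'
#' The generator draws one sub-seed per patient from a single seeded stream,
#' so enlarging an arm reproduces the original patients bit-for-bit and only
#' appends new ones. The global RNG state is restored on exit.
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort`: list of data.frames `patients`,
#'   `contacts`, `admissions` (long format, keyed by `patient_id`) and the
#'   generating `config`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config(n_intervention = 20,
#'                                              n_comparator = 20))
#' table(coh$patients$arm)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n_total <- config$intervention$n + config$comparator$n
  patient_seeds <- sample.int(.Machine$integer.max, n_total)

  pieces <- vector("list", n_total)
  k <- 0L
  for (arm_name in c("intervention", "comparator")) {
    cfg <- config[[arm_name]]
    for (i in seq_len(cfg$n)) {
      k <- k + 1L
      set.seed(patient_seeds[k])
      pieces[[k]] <- generate_patient(sprintf("%s_%04d", arm_name, i),
                                      arm_name, cfg, config$followup_months)
    }
  }
  bind <- function(field) {
    parts <- Filter(Negate(is.null), lapply(pieces, `[[`, field))
    if (!length(parts))
      return(data.frame(patient_id = character(0)))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  structure(list(patients = bind("patient"), contacts = bind("contacts"),
                 admissions = bind("admissions"), config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat("Synthetic cohort: ", nrow(x$patients), " patients (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("  ", nrow(x$contacts), " professional contacts, ",
      nrow(x$admissions), " hospital admissions over ",
      x$config$followup_months, " months\n", sep = "")
  invisible(x)
}

#' Packaged default cohort configuration
#'
#' The generator's defaults emulate the evaluated programme's cohort:
#' two arms of 98 and 100 patients aged around 85/83 years, 74%/57% female,
#' with the observed comorbidity prevalences, baseline Barthel/IADL/GDS
#' distributions, follow-up score changes (change SDs recovered from the
#' reported 95% confidence intervals), annual contact rates of 51/53 with
#' the observed professional/setting/planned mixes, and the observed
#' hospitalization profile, over an 8-month follow-up.
#'
#' @param n_intervention,n_comparator arm sizes (defaults 98 and 100).
#' @param seed generator seed.
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function(n_intervention = 98, n_comparator = 100,
                                  seed = 1L) {
  int <- arm_cohort_config(
    n = n_intervention, age_mean = 85.5, age_sd = 5.4, female_fraction = 0.74,
    comorbidity_prevalence = c(
      myocardial_infarction = 0.173, congestive_heart_failure = 0.622,
      peripheral_vascular_disease = 0.010, cerebrovascular_disease = 0.443,
      dementia = 0.031, chronic_pulmonary_disease = 0.010,
      rheumatic_disease = 0.031, peptic_ulcer_disease = 0.196,
      mild_liver_disease = 0.227, diabetes_uncomplicated = 0.260,
      diabetes_complicated = 0.320, hemiplegia_paraplegia = 0.289,
      renal_disease = 0.010, malignancy = 0.237,
      moderate_severe_liver_disease = 0.031, metastatic_solid_tumor = 0.134),
    score_baseline = list(barthel = c(44.66, 27.37), iadl = c(1.45, 1.74),
                          gds = c(7.23, 3.47)),
    score_change = list(barthel = c(0.14, 23.2), iadl = c(-0.23, 1.05),
                        gds = c(0.28, 3.62)),
    contact_rate = 51.0,
    professional_mix = c(gp = 0.342, specialist = 0.044, nurse = 0.575,
                         other_health = 0.010, social_worker = 0.029,
                         volunteer = 0),
    setting_mix = c(out_of_home = 0.094, home_visit = 0.426,
                    telephone = 0.297, writing = 0.181, other = 0.002),
    planned_prob = 0.932, admission_prob = 0.327, mean_admissions = 0.85,
    los_mean = 5.84, los_sd = 8.81, planned_admission_prob = 0.289)
  comp <- arm_cohort_config(
    n = n_comparator, age_mean = 82.8, age_sd = 6.2, female_fraction = 0.57,
    comorbidity_prevalence = c(
      myocardial_infarction = 0.230, congestive_heart_failure = 0.710,
      peripheral_vascular_disease = 0.030, cerebrovascular_disease = 0.250,
      dementia = 0.050, chronic_pulmonary_disease = 0.030,
      rheumatic_disease = 0.100, peptic_ulcer_disease = 0.160,
      mild_liver_disease = 0.340, diabetes_uncomplicated = 0.270,
      diabetes_complicated = 0.190, hemiplegia_paraplegia = 0.370,
      renal_disease = 0.010, malignancy = 0.090,
      moderate_severe_liver_disease = 0.040, metastatic_solid_tumor = 0.120),
    score_baseline = list(barthel = c(71.58, 27.95), iadl = c(2.94, 2.55),
                          gds = c(6.11, 3.51)),
    score_change = list(barthel = c(-3.23, 10.7), iadl = c(-0.33, 0.65),
                        gds = c(-0.29, 1.51)),
    contact_rate = 53.1,
    professional_mix = c(gp = 0.233, specialist = 0.078, nurse = 0.661,
                         other_health = 0.014, social_worker = 0.015,
                         volunteer = 0),
    setting_mix = c(out_of_home = 0.212, home_visit = 0.259,
                    telephone = 0.202, writing = 0.323, other = 0.003),
    planned_prob = 0.876, admission_prob = 0.45, mean_admissions = 1.12,
    los_mean = 2.3, los_sd = 2.8, planned_admission_prob = 0.321)
  cohort_config(int, comp, followup_months = 8, seed = seed)
}

#' Write / read a cohort as delimited text
#'
#' One `patients.tsv` row per patient, with companion long-format
#' `contacts.tsv` and `admissions.tsv` keyed by `patient_id`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `cohort` object (without the generating config).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(cohort$patients, "patients.tsv")
  w(cohort$contacts, "contacts.tsv")
  w(cohort$admissions, "admissions.tsv")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  r <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing cohort file: ", p, call. = FALSE)
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  structure(list(patients = r("patients.tsv"), contacts = r("contacts.tsv"),
                 admissions = r("admissions.tsv"), config = NULL),
            class = "cohort")
}
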