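#' Default contact durations by setting
#'
#' Assumed hours per professional contact, keyed by contact setting. Contact
#' counts are routinely recorded but their durations are not, so these
#' defaults are explicit modelling assumptions; per-record durations, where
#' available, override them in [contact_cost()].
#'
#' @return named numeric vector of hours.
#' @export
default_contact_durations <- function() {
  c(out_of_home = 0.33, home_visit = 0.75, telephone = 0.17,
    writing = 0.08, other = 0.33)
}

#' Unit costs
#'
#' Monetary valuation inputs in 2016 euros: hourly wages per professional
#' class (full-time-equivalent income including employer social-security
#' contributions), the citizen wage used to monetize patient and informal
#' caregiver time (the statutory minimum interprofessional wage), the cost
#' per hospital bed-day, default contact durations, and the travel burden
#' attributed to each attended out-of-home contact. Specialists are costed
#' at the physician wage and other health-care providers at the nurse wage
#' (no separate wages are available); volunteer care is unmonetized.
#'
#' @param wage_physician,wage_nurse,wage_social,wage_citizen euro/hour.
#' @param bed_day euro per hospital bed-day.
#' @param contact_durations named hours per contact by setting, see
#'   [default_contact_durations()].
#' @param travel_hours_per_contact,travel_cost_per_contact citizen time and
#'   out-of-pocket money per attended out-of-home contact.
#' @param currency_year price year (informational).
#' @return object of class `unit_costs`.
#' @export
unit_costs <- function(wage_physician = 29.23, wage_nurse = 20.79,
                       wage_social = 18.19, wage_citizen = 6.07,
                       bed_day = 733.56,
                       contact_durations = default_contact_durations(),
                       travel_hours_per_contact = 0.5,
                       travel_cost_per_contact = 0,
                       currency_year = 2016) {
  vals <- c(wage_physician, wage_nurse, wage_social, wage_citizen, bed_day,
            contact_durations, travel_hours_per_contact, travel_cost_per_contact)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all unit costs and durations must be >= 0", call. = FALSE)
  structure(list(wage_physician = wage_physician, wage_nurse = wage_nurse,
                 wage_social = wage_social, wage_citizen = wage_citizen,
                 bed_day = bed_day, contact_durations = contact_durations,
                 travel_hours_per_contact = travel_hours_per_contact,
                 travel_cost_per_contact = travel_cost_per_contact,
                 currency_year = currency_year),
            class = "unit_costs")
}

# hourly wage per professional class; volunteers cost 0
professional_wage <- function(professional, uc) {
  wages <- c(gp = uc$wage_physician, specialist = uc$wage_physician,
             nurse = uc$wage_nurse, other_health = uc$wage_nurse,
             social_worker = uc$wage_social, volunteer = 0)
  unknown <- setdiff(unique(professional), names(wages))
  if (length(unknown))
    stop("no wage rule for professional class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  unname(wages[professional])
}

#' Cost of professional contacts
#'
#' Duration times the hourly wage of the professional class, per contact
#' record. Missing durations fall back to the setting defaults of the unit
#' costs; volunteer contacts cost zero.
#'
#' @param contacts data.frame with columns `professional`, `setting` and
#'   optionally `duration` (hours).
#' @param uc a [unit_costs()].
#' @return numeric vector, euro per record.
#' @export
#' @examples
#' contact_cost(data.frame(professional = "gp", setting = "home_visit",
#'                         duration = 0.5), unit_costs())
contact_cost <- function(contacts, uc = unit_costs()) {
  stopifnot(inherits(uc, "unit_costs"))
  if (!nrow(contacts)) return(numeric(0))
  dur <- if ("duration" %in% names(contacts)) contacts$duration
         else rep(NA_real_, nrow(contacts))
  need <- is.na(dur)
  if (any(need)) {
    unknown <- setdiff(unique(contacts$setting[need]), names(uc$contact_durations))
    if (length(unknown))
      stop("no default duration for setting: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    dur[need] <- uc$contact_durations[contacts$setting[need]]
  }
  if (any(dur <= 0)) stop("contact durations must be > 0", call. = FALSE)
  dur * professional_wage(contacts$professional, uc)
}

#' Hospitalization cost
#'
#' @param bed_days nonnegative bed-days (vectorised).
#' @param uc a [unit_costs()].
#' @return euro, `bed_days * bed_day cost`.
#' @export
#' @examples
#' hospital_cost(5)
hospital_cost <- function(bed_days, uc = unit_costs()) {
  if (any(bed_days < 0, na.rm = TRUE))
    stop("bed_days must be >= 0", call. = FALSE)
  bed_days * uc$bed_day
}

#' Monetized patient / informal-caregiver time
#'
#' @param hours nonnegative hours (vectorised).
#' @param uc a [unit_costs()].
#' @return euro, `hours * citizen wage`.
#' @export
#' @examples
#' citizen_time_cost(2)
citizen_time_cost <- function(hours, uc = unit_costs()) {
  if (any(hours < 0, na.rm = TRUE)) stop("hours must be >= 0", call. = FALSE)
  hours * uc$wage_citizen
}

#' Homogenize a follow-up cost to euro per patient-year
#'
#' @param amount euro accrued over the follow-up.
#' @param followup_months follow-up duration in months (> 0).
#' @return euro per patient-year, `amount * 12 / followup_months`.
#' @export
#' @examples
#' annualize(1000, 8)
annualize <- function(amount, followup_months) {
  if (any(followup_months <= 0))
    stop("followup_months must be > 0", call. = FALSE)
  amount * 12 / followup_months
}

#' Programme costs of the intervention
#'
#' @param one_off euro per patient, incurred once at implementation.
#' @param recurring euro per patient-year of service operation.
#' @return object of class `program_costs`.
#' @export
program_costs <- function(one_off = 1268.89, recurring = 230.40) {
  if (one_off < 0 || recurring < 0)
    stop("programme costs must be >= 0", call. = FALSE)
  structure(list(one_off = one_off, recurring = recurring),
            class = "program_costs")
}

#' Programme costs attributed to an arm
#'
#' The intervention arm carries the configured one-off and recurring
#' programme costs; the comparator carries none.
#'
#' @param program a [program_costs()].
#' @param arm `"intervention"` or `"comparator"`.
#' @return named numeric `c(one_off, recurring)`.
#' @export
#' @examples
#' arm_program_costs(program_costs(), "comparator")
arm_program_costs <- function(program, arm = c("intervention", "comparator")) {
  stopifnot(inherits(program, "program_costs"))
  arm <- match.arg(arm)
  if (arm == "intervention") c(one_off = program$one_off,
                               recurring = program$recurring)
  else c(one_off = 0, recurring = 0)
}

#' Per-patient costs under a costing perspective
#'
#' Monetizes each patient's resource use and homogenizes it to euro per
#' patient-year. The health-care perspective covers professional contacts
#' and hospital bed-days. The societal perspective additionally values, for
#' intervention patients, the time they spend operating the telehealth
#' platform and, for comparator patients, the travel time and out-of-pocket
#' cost of attended out-of-home contacts (the intervention avoids these
#' journeys, so they are charged to the comparator).
#'
#' @param cohort a `cohort` object.
#' @param uc a [unit_costs()].
#' @param perspective `"healthcare"` or `"societal"`.
#' @param platform_hours_per_year assumed platform-usage time of an
#'   intervention patient (hours per patient-year).
#' @return data.frame, one row per patient: `patient_id`, `arm`,
#'   `contact_cost`, `hospital_cost`, `time_cost`, `travel_cost`, `total`,
#'   all euro per patient-year.
#' @export
patient_perspective_costs <- function(cohort, uc = unit_costs(),
                                      perspective = c("healthcare", "societal"),
                                      platform_hours_per_year = 48) {
  stopifnot(inherits(cohort, "cohort"))
  perspective <- match.arg(perspective)
  p <- cohort$patients
  m <- p$followup_months

  cc <- contact_cost(cohort$contacts, uc)
  contact_by_pat <- if (length(cc))
    tapply(cc, cohort$contacts$patient_id, sum) else numeric(0)
  hc <- if (nrow(cohort$admissions))
    tapply(hospital_cost(cohort$admissions$bed_days, uc),
           cohort$admissions$patient_id, sum) else numeric(0)
  pick <- function(tab, id) ifelse(id %in% names(tab), tab[id], 0)

  out <- data.frame(patient_id = p$id, arm = p$arm,
                    contact_cost = annualize(unname(pick(contact_by_pat, p$id)), m),
                    hospital_cost = annualize(unname(pick(hc, p$id)), m),
                    time_cost = 0, travel_cost = 0,
                    stringsAsFactors = FALSE)

  if (perspective == "societal") {
    out$time_cost[out$arm == "intervention"] <-
      citizen_time_cost(platform_hours_per_year, uc)
    ooh <- cohort$contacts[cohort$contacts$setting == "out_of_home", , drop = FALSE]
    if (nrow(ooh)) {
      per_contact <- citizen_time_cost(uc$travel_hours_per_contact, uc) +
        uc$travel_cost_per_contact
      n_ooh <- tapply(rep(1, nrow(ooh)), ooh$patient_id, sum)
      comp <- out$arm == "comparator"
      out$travel_cost[comp] <-
        annualize(unname(pick(n_ooh, out$patient_id[comp])) * per_contact,
                  m[comp])
    }
  }
  out$total <- out$contact_cost + out$hospital_cost + out$time_cost +
    out$travel_cost
  out
}

#' State-conditional mean annual costs
#'
#' Mean annualized per-patient total cost within each disease-stage stratum
#' of one arm — the per-state cost inputs of the Markov model. An empty
#' stratum is flagged and its cost reported as `NA`.
#'
#' @param patient_costs output of [patient_perspective_costs()], restricted
#'   to one arm or combined with `classification` across arms.
#' @param classification character vector aligned with `patient_costs`
#'   rows: `"worsened"` / `"stable_or_improved"` (see
#'   [classify_transition()]); `NA` rows are excluded.
#' @return data.frame: `state` (`baseline`, `deteriorated`), `mean_cost`,
#'   `n`, `empty`.
#' @export
state_conditional_costs <- function(patient_costs, classification) {
  if (nrow(patient_costs) != length(classification))
    stop("classification must align with patient_costs rows", call. = FALSE)
  keep <- !is.na(classification)
  pc <- patient_costs[keep, , drop = FALSE]
  cls <- classification[keep]
  state_of <- c(stable_or_improved = "baseline", worsened = "deteriorated")
  res <- lapply(c("baseline", "deteriorated"), function(st) {
    tot <- pc$total[state_of[cls] == st]
    data.frame(state = st,
               mean_cost = if (length(tot)) mean(tot) else NA_real_,
               n = length(tot), empty = !length(tot),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Aggregated cost report
#'
#' Per-arm, per-perspective mean annual costs of a cohort, with the
#' disease-stage breakdown.
#'
#' @param cohort a `cohort` object.
#' @param uc a [unit_costs()].
#' @param instrument,threshold disease-stage classification settings, see
#'   [classify_transition()].
#' @return data.frame with one row per arm x perspective x state plus an
#'   `all` state row per arm and perspective.
#' @export
cost_report <- function(cohort, uc = unit_costs(), instrument = "barthel",
                        threshold = 0) {
  rows <- list()
  for (persp in c("healthcare", "societal")) {
    pc <- patient_perspective_costs(cohort, uc, persp)
    for (arm in unique(pc$arm)) {
      sel <- pc$arm == arm
      p <- cohort$patients[match(pc$patient_id[sel], cohort$patients$id), ]
      cls <- classify_transition(p[[paste0(instrument, "_0")]],
                                 p[[paste0(instrument, "_1")]], threshold)
      scc <- state_conditional_costs(pc[sel, , drop = FALSE], cls)
      scc$arm <- arm; scc$perspective <- persp
      all_row <- data.frame(state = "all", mean_cost = mean(pc$total[sel]),
                            n = sum(sel), empty = FALSE, arm = arm,
                            perspective = persp, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- rbind(scc, all_row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("arm", "perspective", "state", "mean_cost", "n", "empty")]
}
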