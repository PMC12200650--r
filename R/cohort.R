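# Calendar constants used across the cohort and phenotyping rules.
# Whole-day arithmetic throughout: "12 months" = 365 days, "6 months" =
# 183 days, "5 years" = 1825 days, "10 years" = 3650 days (leap days
# ignored) — fixed so every window is exactly testable.
DAYS_YEAR <- 365L
DAYS_6M <- 183L
DAYS_5Y <- 1825L
DAYS_10Y <- 3650L

year_of <- function(d) as.integer(format(d, "%Y"))

#' Registered-patient denominator per calendar year
#'
#' A patient counts towards year `y` when registered for at least one day
#' of `y` and with at least 365 days of registration behind them by the
#' end of `y` (so newly registered patients without an evaluable washout
#' are not in the denominator).
#'
#' @param patients Patient table with `registration_start`,
#'   `registration_end`.
#' @param years Integer vector of calendar years.
#' @return Named integer vector, one count per year.
#' @export
registered_patients_by_year <- function(patients, years) {
  out <- vapply(years, function(y) {
    y_start <- as.Date(sprintf("%d-01-01", y))
    y_end <- as.Date(sprintf("%d-12-31", y))
    sum(patients$registration_start <= y_end - DAYS_YEAR &
          patients$registration_end >= y_start)
  }, integer(1))
  stats::setNames(out, years)
}

#' Find incident opioid index dates (new-user design)
#'
#' An issue date qualifies as an incident index when the patient has no
#' opioid issue in the preceding 365 days (first-ever issues qualify), is
#' aged 18 or over in the index year (year-of-birth resolution: age =
#' index year minus birth year), has at least 365 days of registration
#' before the index, and the index falls inside the study window. A
#' patient may contribute several index events across the study, each with
#' its own qualifying washout.
#'
#' @param clean_rx Clean prescriptions from [prepare_prescriptions()].
#' @param patients Patient table with `patient_id`, `birth_year`,
#'   `registration_start`.
#' @param study_start,study_end Study window (Dates).
#' @return Data.frame of candidate index events: `patient_id`,
#'   `index_date`, `index_year`.
#' @export
find_incident_index_dates <- function(clean_rx, patients,
                                      study_start, study_end) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  empty <- data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      index_year = integer(0))
  if (nrow(clean_rx) == 0) return(empty)

  # distinct issue dates per patient, sorted
  iss <- unique(clean_rx[, c("patient_id", "supply_start")])
  names(iss)[2] <- "issue_date"
  iss <- iss[order(iss$patient_id, iss$issue_date), ]
  same_prev <- c(FALSE, iss$patient_id[-1] == iss$patient_id[-nrow(iss)])
  prev_date <- c(as.Date(NA), iss$issue_date[-nrow(iss)])
  prev_date[!same_prev] <- NA
  gap_ok <- is.na(prev_date) |
    as.integer(iss$issue_date - prev_date) >= DAYS_YEAR + 1L

  pidx <- match(iss$patient_id, patients$patient_id)
  reg_ok <- as.integer(iss$issue_date -
                         patients$registration_start[pidx]) >= DAYS_YEAR
  iy <- year_of(iss$issue_date)
  age_ok <- (iy - patients$birth_year[pidx]) >= 18L
  in_window <- iss$issue_date >= study_start & iss$issue_date <= study_end

  keep <- gap_ok & reg_ok & age_ok & in_window
  if (!any(keep)) return(empty)
  out <- data.frame(patient_id = iss$patient_id[keep],
                    index_date = iss$issue_date[keep],
                    index_year = iy[keep])
  rownames(out) <- NULL
  out
}

#' Apply chronic-pain inclusion and cancer exclusion rules
#'
#' Retains index events with at least one chronic non-cancer pain (CNCP)
#' diagnosis any time before or up to 183 days after the index, and no
#' cancer diagnosis other than non-melanoma skin cancer in the 3650 days
#' up to and including the index.
#'
#' @param events Candidate events from [find_incident_index_dates()].
#' @param diagnoses Diagnosis table with `patient_id`, `date`, `category`;
#'   categories `"CNCP"`, `"cancer"` and `"NMSC"` drive the rules.
#' @return The retained events.
#' @export
apply_cncp_and_cancer_rules <- function(events, diagnoses) {
  if (nrow(events) == 0) return(events)
  cncp <- diagnoses[diagnoses$category == "CNCP", ]
  first_cncp <- tapply(cncp$date, cncp$patient_id, min)
  fc <- as.Date(unname(first_cncp[events$patient_id]),
                origin = "1970-01-01")
  cncp_ok <- !is.na(fc) & fc <= events$index_date + DAYS_6M

  cancer <- diagnoses[diagnoses$category == "cancer", ]
  cancer_by_pat <- split(cancer$date, cancer$patient_id)
  cancer_hit <- mapply(function(pid, idx) {
    d <- cancer_by_pat[[pid]]
    !is.null(d) && any(d >= idx - DAYS_10Y & d <= idx)
  }, events$patient_id, events$index_date)

  out <- events[cncp_ok & !cancer_hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Determine end of follow-up and censoring reason
#'
#' Follow-up runs from the index to the earliest of: death, the first
#' cancer diagnosis after the index, transfer out of the practice
#' (registration end before the practice's last collection date), the
#' practice's last data collection date, or the study end. Ties are broken
#' deterministically in that order.
#'
#' @param events Index events (`patient_id`, `index_date`, `index_year`).
#' @param patients Patient table with `registration_end`, `death_date`,
#'   `last_collection_date`.
#' @param diagnoses Diagnosis table (cancer dates censor follow-up).
#' @param study_end Study end date.
#' @return Events with `followup_end` and `censor_reason` appended.
#' @export
compute_followup_end <- function(events, patients, diagnoses, study_end) {
  study_end <- as.Date(study_end)
  if (nrow(events) == 0) {
    events$followup_end <- as.Date(character(0))
    events$censor_reason <- character(0)
    return(events)
  }
  pidx <- match(events$patient_id, patients$patient_id)
  cancer <- diagnoses[diagnoses$category == "cancer", ]
  cancer_by_pat <- split(cancer$date, cancer$patient_id)
  first_cancer_after <- mapply(function(pid, idx) {
    d <- cancer_by_pat[[pid]]
    d <- d[d > idx]
    if (length(d) == 0) NA_real_ else as.numeric(min(d))
  }, events$patient_id, events$index_date)

  reg_end <- patients$registration_end[pidx]
  last_coll <- patients$last_collection_date[pidx]
  transfer <- as.Date(ifelse(reg_end < last_coll, as.numeric(reg_end), NA),
                      origin = "1970-01-01")
  # candidate matrix ordered by tie-break priority
  cand <- cbind(death = as.numeric(patients$death_date[pidx]),
                cancer = first_cancer_after,
                transfer = as.numeric(transfer),
                last_collection = as.numeric(last_coll),
                study_end = as.numeric(study_end))
  reasons <- colnames(cand)
  pick <- apply(cand, 1, function(row) {
    j <- which(row == min(row, na.rm = TRUE))[1]  # first = highest priority
    c(row[j], j)
  })
  events$followup_end <- as.Date(pick[1, ], origin = "1970-01-01")
  events$censor_reason <- reasons[pick[2, ]]
  if (any(events$followup_end < events$index_date)) {
    stop("follow-up end precedes index date for ",
         sum(events$followup_end < events$index_date), " event(s)")
  }
  events
}

#' Build the eligible incident cohort from a prepared dataset
#'
#' Chains [find_incident_index_dates()],
#' [apply_cncp_and_cancer_rules()] and [compute_followup_end()].
#'
#' @param clean_rx Clean prescriptions.
#' @param patients,diagnoses Source tables.
#' @param study_start,study_end Study window.
#' @return Index-event data.frame with follow-up end and censoring reason.
#' @export
build_cohort <- function(clean_rx, patients, diagnoses,
                         study_start, study_end) {
  events <- find_incident_index_dates(clean_rx, patients,
                                      study_start, study_end)
  events <- apply_cncp_and_cancer_rules(events, diagnoses)
  compute_followup_end(events, patients, diagnoses, study_end)
}
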