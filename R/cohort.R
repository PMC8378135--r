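#' Index date of a single patient
#'
#' The cohort entry (index) date is the dispense date of the patient's first
#' antipsychotic claim inside the accrual window.  Patients whose claim
#' history starts before the window are caught downstream by the washout
#' exclusion in [build_cohort()], so membership does not depend on whether
#' "first claim" is read as first-ever or first-in-window.
#'
#' @param claims Claims of one patient, sorted by dispense date.
#' @param config A [study_config()] object.
#' @return The index `Date`, or `NA` if the patient has no in-window claim.
#' @export
find_index <- function(claims, config = study_config()) {
  if (length(unique(claims$patient_id)) > 1L) {
    stop("contract error: find_index expects claims of a single patient",
         call. = FALSE)
  }
  d <- claims$dispense_date
  inw <- d >= config$accrual_start & d <= config$accrual_end
  if (!any(inw)) return(as.Date(NA))
  min(d[inw])
}

#' Build the new-user cohort
#'
#' Applies the inclusion/exclusion cascade to every patient with an in-window
#' claim (a *candidate*), in this fixed precedence:
#' `no_dementia` -> `under_age` (completed years at index below
#' `min_age_years`) -> `prior_use` (any antipsychotic claim strictly inside
#' `(index - washout_days, index)`) -> `no_subsequent_rx` (no claim strictly
#' after index within `followup_days`).  Retained members are followed from
#' index to death or `index + followup_days`, whichever comes first.
#'
#' @param patients Patient table from [read_patients()] / [as_patients()].
#' @param claims Claims table (cohort logic uses dispense dates only, so raw
#'   or cleaned claims give identical cohorts).
#' @param config A [study_config()] object.
#' @return `list(members, exclusions)`. `members`: one row per retained
#'   patient with `patient_id`, `index_date`, `followup_end`, `exit_reason`
#'   (`end_of_study` or `death`).  `exclusions`: one row per candidate with
#'   `patient_id`, `index_date`, and `reason` (`retained` or the single
#'   first-triggering exclusion reason).
#' @export
build_cohort <- function(patients, claims, config = study_config()) {
  unknown <- setdiff(unique(claims$patient_id), patients$patient_id)
  if (length(unknown)) {
    stop("data-integrity error: claims reference patient(s) absent from the ",
         "patient table: ", paste(utils::head(sort(unknown), 10), collapse = ", "),
         call. = FALSE)
  }
  d <- claims$dispense_date
  inw <- d >= config$accrual_start & d <= config$accrual_end
  idx_by_patient <- tapply(as.integer(d)[inw], claims$patient_id[inw], min)
  candidates <- names(idx_by_patient)
  index_date <- as.Date(as.integer(idx_by_patient), origin = "1970-01-01")

  prow <- match(candidates, patients$patient_id)
  birth <- patients$birth_date[prow]
  death <- patients$death_date[prow]
  dementia <- patients$dementia[prow]
  age <- age_completed_years(birth, index_date)

  cid <- match(claims$patient_id, candidates)  # NA for non-candidates
  rel <- as.integer(d) - as.integer(idx_by_patient)[cid]
  has_prior <- tabulate_flag(cid, rel > -config$washout_days & rel < 0,
                             length(candidates))
  has_subsequent <- tabulate_flag(cid, rel > 0 & rel <= config$followup_days,
                                  length(candidates))

  reason <- rep("retained", length(candidates))
  reason[!has_subsequent] <- "no_subsequent_rx"
  reason[has_prior] <- "prior_use"
  reason[age < config$min_age_years] <- "under_age"
  reason[!dementia] <- "no_dementia"

  exclusions <- data.frame(patient_id = candidates, index_date = index_date,
                           reason = reason, stringsAsFactors = FALSE)
  keep <- reason == "retained"
  end_study <- index_date + config$followup_days
  died <- !is.na(death) & death <= end_study
  members <- data.frame(
    patient_id = candidates[keep],
    index_date = index_date[keep],
    followup_end = as.Date(ifelse(died[keep], death[keep], end_study[keep]),
                           origin = "1970-01-01"),
    exit_reason = ifelse(died[keep], "death", "end_of_study"),
    stringsAsFactors = FALSE
  )
  rownames(members) <- rownames(exclusions) <- NULL
  list(members = members, exclusions = exclusions)
}

# per-group any(flag) over groups indexed 1..n (NA group indices dropped)
tabulate_flag <- function(group_idx, flag, n) {
  ok <- !is.na(group_idx) & flag
  tabulate(group_idx[ok], nbins = n) > 0
}

#' Is a cohort member on therapy at a timepoint?
#'
#' A member is active at `index + timepoint_days` when follow-up reaches the
#' timepoint (the patient is alive and under observation) and at least one
#' eligible claim covers it under the cleaned fields (see
#' [eligible_claims()]).
#'
#' @param member One row of the `members` table from [build_cohort()].
#' @param claims Claims of that patient (cleaned).
#' @param timepoint_days One of `config$timepoints_days`.
#' @param config A [study_config()] object.
#' @return `TRUE` or `FALSE`.
#' @export
active_at <- function(member, claims, timepoint_days, config = study_config()) {
  if (!timepoint_days %in% config$timepoints_days) {
    stop("contract error: timepoint ", timepoint_days,
         " is not in config$timepoints_days", call. = FALSE)
  }
  if (member$followup_end < member$index_date + timepoint_days) return(FALSE)
  claims <- claims[claims$patient_id == member$patient_id, , drop = FALSE]
  nrow(eligible_claims(claims, member$index_date, timepoint_days, config)) > 0L
}
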