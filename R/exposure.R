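#' Per-claim daily dose in mg of drug
#'
#' The daily dose implied by a claim is the total dispensed drug mass spread
#' evenly over the supply period: `strength_mg * quantity / days_supply`.
#' The same construction applies to oral, short-acting, and long-acting
#' claims, which makes depot doses commensurable with daily tablets.
#'
#' @param claims A claims data frame.
#' @param use_cleaned Use the cleaned quantity/day's-supply fields (`TRUE`,
#'   default) or the raw ones.
#' @return Numeric vector, mg of drug per day per claim.
#' @export
daily_dose_mg <- function(claims, use_cleaned = TRUE) {
  q <- if (use_cleaned) claims$cleaned_quantity else claims$quantity
  ds <- if (use_cleaned) claims$cleaned_days_supply else claims$days_supply
  claims$strength_mg * q / ds
}

#' Per-claim chlorpromazine-equivalent daily dose
#'
#' Multiplies each claim's daily dose by its (drug, formulation) conversion
#' factor from the equivalence table.
#'
#' @inheritParams daily_dose_mg
#' @param table Equivalence table (see [read_equivalence_table()]).
#' @return Numeric vector, mg chlorpromazine-equivalent per day per claim.
#'   Unmapped drugs raise one error listing all of them.
#' @export
cpz_equivalent_mg <- function(claims, table = default_equivalence_table(),
                              use_cleaned = TRUE) {
  daily_dose_mg(claims, use_cleaned) *
    cpz_factor(table, claims$drug, claims$formulation)
}

#' Claims eligible to contribute exposure at a timepoint
#'
#' At initiation (`timepoint_days = 0`) only claims dispensed exactly on the
#' index date are eligible.  At a later timepoint `t = index +
#' timepoint_days`, a claim is eligible when it was dispensed inside the
#' half-open lookback window `(t - lookback_days, t]` *and* its supply covers
#' the timepoint under the half-open coverage convention
#' `dispense <= t < dispense + days_supply`.
#'
#' @param claims Claims of one patient, sorted.
#' @param index_date The patient's cohort entry date.
#' @param timepoint_days Integer offset from index, `>= 0`.
#' @inheritParams daily_dose_mg
#' @param config A [study_config()] object.
#' @return The eligible subset of `claims`.
#' @export
eligible_claims <- function(claims, index_date, timepoint_days,
                            config = study_config(), use_cleaned = TRUE) {
  d <- claims$dispense_date
  if (timepoint_days == 0L) {
    return(claims[d == index_date, , drop = FALSE])
  }
  t_date <- index_date + timepoint_days
  ds <- if (use_cleaned) claims$cleaned_days_supply else claims$days_supply
  in_window <- d > t_date - config$lookback_days & d <= t_date
  covers <- t_date < d + ds
  claims[in_window & covers, , drop = FALSE]
}

#' Route class of a set of contributing claims
#'
#' Oral and rectal claims fold into the `oral` stratum; immediate injectables
#' are `regular_injectable`; long-acting injectables are
#' `long_acting_injectable`.  More than one distinct category yields
#' `multiple`.
#'
#' @param claims Non-empty claims data frame.
#' @return One of `"oral"`, `"regular_injectable"`,
#'   `"long_acting_injectable"`, `"multiple"`.
#' @export
classify_route <- function(claims) {
  if (nrow(claims) == 0L) {
    stop("contract error: classify_route requires a non-empty claim set",
         call. = FALSE)
  }
  cat <- ifelse(claims$route %in% c("oral", "rectal"), "oral",
                ifelse(claims$formulation == "long_acting",
                       "long_acting_injectable", "regular_injectable"))
  u <- unique(cat)
  if (length(u) == 1L) u else "multiple"
}

#' Assess chlorpromazine-equivalent exposure for a cohort
#'
#' For every cohort member and every configured timepoint still inside the
#' member's follow-up, sums the chlorpromazine-equivalent daily doses of all
#' eligible claims, regardless of drug or route.  Totals are computed twice
#' — once from the raw fields and once from the cleaned fields, with
#' eligibility re-derived under each field set — so the impact of cleaning
#' on each patient's measured dose is visible.  A patient-timepoint with no
#' cleaned-eligible claims emits no assessment (the patient is off therapy).
#'
#' @param members Cohort members from [build_cohort()].
#' @param claims Cleaned claims (see [clean_claims()]).
#' @param table Equivalence table.
#' @param config A [study_config()] object.
#' @param timepoints_days Timepoints to assess (default
#'   `config$timepoints_days`).
#' @return A data frame with one row per (patient, timepoint):
#'   `patient_id`, `timepoint_days`, `route_class`, `n_claims`, `n_drugs`
#'   (distinct contributing drugs), `contributing_claim_ids`
#'   (";"-separated), `total_cpz_mg_raw`, `total_cpz_mg_cleaned`, and
#'   `modified_by_cleaning` (`TRUE` when the two totals differ by more than
#'   `config$dose_change_tolerance_mg`).
#' @export
assess_exposure <- function(members, claims, table = default_equivalence_table(),
                            config = study_config(),
                            timepoints_days = config$timepoints_days) {
  claims <- claims[claims$patient_id %in% members$patient_id, , drop = FALSE]
  mrow <- match(claims$patient_id, members$patient_id)
  idx <- members$index_date[mrow]
  fend <- members$followup_end[mrow]
  cpz_clean <- cpz_equivalent_mg(claims, table, use_cleaned = TRUE)
  cpz_raw <- cpz_equivalent_mg(claims, table, use_cleaned = FALSE)
  d <- claims$dispense_date

  out <- vector("list", length(timepoints_days))
  for (k in seq_along(timepoints_days)) {
    tp <- timepoints_days[k]
    t_date <- idx + tp
    assessed <- fend >= t_date
    if (tp == 0L) {
      elig_c <- elig_r <- assessed & d == idx
    } else {
      in_window <- d > t_date - config$lookback_days & d <= t_date
      elig_c <- assessed & in_window & t_date < d + claims$cleaned_days_supply
      elig_r <- assessed & in_window & t_date < d + claims$days_supply
    }
    pids <- sort(unique(claims$patient_id[elig_c]))
    if (!length(pids)) next
    gc_ <- match(claims$patient_id, pids)
    tot_c <- sum_by(cpz_clean[elig_c], gc_[elig_c], length(pids))
    tot_r <- sum_by(cpz_raw[elig_r], gc_[elig_r], length(pids))
    route <- vapply(split(seq_len(nrow(claims))[elig_c], gc_[elig_c]),
                    function(i) classify_route(claims[i, , drop = FALSE]),
                    character(1))
    n_claims <- tabulate(gc_[elig_c], nbins = length(pids))
    n_drugs <- vapply(split(claims$drug[elig_c], gc_[elig_c]),
                      function(x) length(unique(x)), integer(1))
    ids <- vapply(split(claims$claim_id[elig_c], gc_[elig_c]),
                  function(x) paste(x, collapse = ";"), character(1))
    out[[k]] <- data.frame(
      patient_id = pids,
      timepoint_days = tp,
      route_class = as.character(route),
      n_claims = n_claims,
      n_drugs = as.integer(n_drugs),
      contributing_claim_ids = as.character(ids),
      total_cpz_mg_raw = tot_r,
      total_cpz_mg_cleaned = tot_c,
      modified_by_cleaning =
        abs(tot_c - tot_r) > config$dose_change_tolerance_mg,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(patient_id = character(0), timepoint_days = integer(0),
                      route_class = character(0), n_claims = integer(0),
                      n_drugs = integer(0),
                      contributing_claim_ids = character(0),
                      total_cpz_mg_raw = numeric(0),
                      total_cpz_mg_cleaned = numeric(0),
                      modified_by_cleaning = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

sum_by <- function(x, group_idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, group_idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}
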