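#' Study configuration
#'
#' All tunable constants of the cleaning, cohort, and exposure rules live in
#' a single configuration object so that jurisdiction-specific variants can be
#' expressed without touching code.
#'
#' @param accrual_start,accrual_end Calendar bounds of the accrual window:
#'   a patient enters the cohort on the date of their first in-window
#'   antipsychotic claim.
#' @param washout_days Length in days of the pre-index washout; any
#'   antipsychotic claim strictly inside `(index - washout_days, index)`
#'   excludes the patient as a prevalent user. Default 365.
#' @param min_age_years Minimum age, in completed years at the index date.
#'   Default 66, which guarantees at least one observable year of
#'   prescription history in a drug plan covering ages 65 and over.
#' @param followup_days Follow-up horizon after the index date. Default 365.
#' @param timepoints_days Integer offsets (days from index) at which exposure
#'   is assessed. Defaults `c(0, 182, 365)`: initiation, month 6, month 12.
#' @param lookback_days Length of the half-open lookback window
#'   `(t - lookback_days, t]` within which a dispensing must fall to be
#'   eligible at a follow-up timepoint `t`. Default 100.
#' @param next_fill_window_days Maximum gap, in days (inclusive), to the next
#'   same-drug fill for the oral/rectal day's-supply value to be trusted.
#'   Default 100.
#' @param oral_fallback_divisor Divisor applied to the dispensed quantity when
#'   the oral/rectal day's supply cannot be trusted; 5 units per day is the
#'   maximum plausible dosing rate for any antipsychotic, making the fallback
#'   deliberately conservative (it can only lower the implied daily dose).
#' @param cost_mismatch_tolerance Relative discrepancy between
#'   `quantity * unit_cost` and `total_cost` above which the short-acting
#'   injectable quantity is repaired from the costs. Default 0.05.
#' @param dose_change_tolerance_mg Absolute difference (mg/day) between the
#'   raw-field and cleaned-field total equivalent dose above which an
#'   assessment counts as modified by cleaning. Default 1e-9.
#'
#' @return An object of class `cpz_config` (a validated named list).
#' @seealso [read_study_config()] to load the same fields from a YAML file.
#' @export
study_config <- function(accrual_start = as.Date("2009-01-01"),
                         accrual_end = as.Date("2012-12-31"),
                         washout_days = 365L,
                         min_age_years = 66L,
                         followup_days = 365L,
                         timepoints_days = c(0L, 182L, 365L),
                         lookback_days = 100L,
                         next_fill_window_days = 100L,
                         oral_fallback_divisor = 5,
                         cost_mismatch_tolerance = 0.05,
                         dose_change_tolerance_mg = 1e-9) {
  cfg <- list(
    accrual_start = as.Date(accrual_start),
    accrual_end = as.Date(accrual_end),
    washout_days = as.integer(washout_days),
    min_age_years = as.integer(min_age_years),
    followup_days = as.integer(followup_days),
    timepoints_days = as.integer(timepoints_days),
    lookback_days = as.integer(lookback_days),
    next_fill_window_days = as.integer(next_fill_window_days),
    oral_fallback_divisor = as.numeric(oral_fallback_divisor),
    cost_mismatch_tolerance = as.numeric(cost_mismatch_tolerance),
    dose_change_tolerance_mg = as.numeric(dose_change_tolerance_mg)
  )
  class(cfg) <- "cpz_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cpz_config"))
  if (is.na(cfg$accrual_start) || is.na(cfg$accrual_end) ||
      cfg$accrual_end < cfg$accrual_start) {
    stop("config error: accrual window must be a valid [start, end] date pair",
         call. = FALSE)
  }
  pos <- c(washout_days = cfg$washout_days, min_age_years = cfg$min_age_years,
           followup_days = cfg$followup_days, lookback_days = cfg$lookback_days,
           next_fill_window_days = cfg$next_fill_window_days,
           oral_fallback_divisor = cfg$oral_fallback_divisor)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop("config error: fields must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(cfg$timepoints_days)) ||
      any(cfg$timepoints_days < 0 | cfg$timepoints_days > cfg$followup_days)) {
    stop("config error: timepoints_days must lie within [0, followup_days]",
         call. = FALSE)
  }
  if (!is.finite(cfg$cost_mismatch_tolerance) || cfg$cost_mismatch_tolerance < 0) {
    stop("config error: cost_mismatch_tolerance must be >= 0", call. = FALSE)
  }
  if (!is.finite(cfg$dose_change_tolerance_mg) || cfg$dose_change_tolerance_mg < 0) {
    stop("config error: dose_change_tolerance_mg must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a study configuration from YAML
#'
#' Fields absent from the file fall back to the [study_config()] defaults.
#'
#' @param path Path to a YAML file whose keys match [study_config()] arguments.
#' @return A `cpz_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("config error: unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(study_config, raw)
}

#' @export
print.cpz_config <- function(x, ...) {
  cat("Study configuration (cpz_config)\n")
  cat(sprintf("  accrual window: %s .. %s\n", x$accrual_start, x$accrual_end))
  cat(sprintf("  washout %d d | min age %d y | follow-up %d d\n",
              x$washout_days, x$min_age_years, x$followup_days))
  cat(sprintf("  timepoints (days): %s\n",
              paste(x$timepoints_days, collapse = ", ")))
  cat(sprintf("  lookback %d d | next-fill window %d d | fallback divisor %g\n",
              x$lookback_days, x$next_fill_window_days, x$oral_fallback_divisor))
  cat(sprintf("  cost mismatch tol %g | dose change tol %g mg\n",
              x$cost_mismatch_tolerance, x$dose_change_tolerance_mg))
  invisible(x)
}

#' Canonicalize a drug name
#'
#' Claims data dialects disagree on case and whitespace; all matching on
#' "the same medication name" uses this canonical token.
#'
#' @param x Character vector of drug names.
#' @return Lower-cased, trimmed names with internal whitespace collapsed.
#' @export
canonical_drug <- function(x) {
  gsub("\\s+", " ", tolower(trimws(as.character(x))))
}

# round half-up to an integer; day's-supply fallbacks must not round to even
round_half_up <- function(x) floor(x + 0.5)

# completed years between two dates (birthday not yet reached => year not counted)
age_completed_years <- function(birth, at) {
  b <- as.POSIXlt(birth)
  a <- as.POSIXlt(at)
  yrs <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - before_birthday)
}
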