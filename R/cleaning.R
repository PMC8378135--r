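#' Route-specific claims cleaning
#'
#' Dispensing claims for antipsychotics carry two fragile fields: the day's
#' supply and (for injectables) the dispensed quantity.  Each administration
#' route gets its own repair rule:
#'
#' * **Oral and rectal** ([clean_oral_rectal()]): the day's supply is trusted
#'   when the next fill of the same drug arrives within
#'   `next_fill_window_days` (default 100, inclusive); otherwise it is
#'   replaced by `quantity / oral_fallback_divisor` (default 5, the maximum
#'   plausible units per day), rounded half-up and floored at 1 day.
#' * **Long-acting injectables** ([clean_long_acting()]): with minimum dosing
#'   interval `m` for the drug and gap `g` (days) to the patient's next
#'   long-acting claim of any drug — keep the day's supply if it exceeds `m`;
#'   set it to `m` when there is no subsequent long-acting claim (or when
#'   `g >= m`); set it to `g` when the next injection arrives earlier than
#'   the minimum interval.
#' * **Short-acting injectables** ([clean_short_acting()]): when the billed
#'   costs are internally inconsistent with the quantity
#'   (relative mismatch of `quantity * unit_cost` vs `total_cost` above
#'   `cost_mismatch_tolerance`), the quantity is repaired to
#'   `total_cost / unit_cost` (2 decimals); the day's supply then follows the
#'   oral rule, dividing the repaired quantity in the fallback.
#'
#' [clean_claims()] dispatches every claim to exactly one rule family by
#' (route, formulation), never alters drugs, strengths, dates, costs, or
#' patient assignment, and is idempotent: a second pass reports zero
#' modifications.
#'
#' @param claims A claims data frame from [as_claims()] / [read_claims()]
#'   (for the family-specific functions: restricted to that family and sorted
#'   by patient, dispense date, claim id).
#' @param intervals Minimum-dosing-interval table
#'   (default [default_interval_table()]); every long-acting drug must have
#'   an entry.
#' @param config A [study_config()] object.
#'
#' @return [clean_claims()] returns `list(claims, report)`: the claims with
#'   `cleaned_quantity` / `cleaned_days_supply` and cumulative modification
#'   flags set, and a per-claim report with the evaluated branches
#'   (`branch_days`, `branch_quantity`), the values before and after this
#'   pass, per-pass modification flags, and `rule_applied` (the modifying
#'   rule or rules joined by `+`, or `"none"`).  The family functions return
#'   the updated claims with a `cleaning_branch` attribute.
#' @name cleaning
NULL

# days to the next strictly later dispense date within each group (NA if none);
# input dates must be ascending within group
next_gap_by_group <- function(group, dates) {
  gap <- rep(NA_real_, length(dates))
  d <- as.integer(dates)
  for (idx in split(seq_along(d), group)) {
    dd <- d[idx]
    u <- unique(dd)
    nxt <- c(u, NA_integer_)[findInterval(dd, u) + 1L]
    gap[idx] <- nxt - dd
  }
  gap
}

assert_family <- function(claims, keep, what) {
  if (!all(keep)) {
    stop("contract error: claims passed to the ", what,
         " rule must all belong to that route/formulation family",
         call. = FALSE)
  }
  if (!is_sorted_claims(claims)) {
    stop("contract error: claims must be sorted by (patient_id, ",
         "dispense_date, claim_id)", call. = FALSE)
  }
}

.oral_days_rule <- function(claims, config, fallback_qty) {
  gap <- next_gap_by_group(paste(claims$patient_id, claims$drug, sep = "\r"),
                           claims$dispense_date)
  keep <- !is.na(gap) & gap <= config$next_fill_window_days
  fb <- pmax(1L, as.integer(round_half_up(
    fallback_qty / config$oral_fallback_divisor)))
  list(ds = as.integer(ifelse(keep, claims$cleaned_days_supply, fb)),
       branch = ifelse(keep, "oral_keep", "oral_fallback"))
}

#' @rdname cleaning
#' @export
clean_oral_rectal <- function(claims, config = study_config()) {
  assert_family(claims, claims$route %in% c("oral", "rectal"), "oral/rectal")
  res <- .oral_days_rule(claims, config, claims$cleaned_quantity)
  finish_family(claims, new_q = claims$cleaned_quantity, new_ds = res$ds,
                branch_days = res$branch, branch_quantity = NA_character_)
}

#' @rdname cleaning
#' @export
clean_long_acting <- function(claims, intervals = default_interval_table(),
                              config = study_config()) {
  assert_family(claims,
                claims$route == "injectable" & claims$formulation == "long_acting",
                "long-acting injectable")
  m <- intervals$min_interval_days[match(claims$drug, intervals$drug)]
  if (anyNA(m)) {
    stop("config error: no minimum dosing interval for drug(s): ",
         paste(sort(unique(claims$drug[is.na(m)])), collapse = ", "),
         call. = FALSE)
  }
  # gap to the next long-acting claim of ANY drug for the same patient
  gap <- next_gap_by_group(claims$patient_id, claims$dispense_date)
  ds0 <- claims$cleaned_days_supply
  keep <- ds0 > m
  new_ds <- ifelse(keep, ds0,
                   ifelse(!is.na(gap) & gap < m, gap, m))
  branch <- ifelse(keep, "la_keep",
                   ifelse(!is.na(gap) & gap < m, "la_set_gap",
                          "la_set_min_interval"))
  finish_family(claims, new_q = claims$cleaned_quantity,
                new_ds = as.integer(new_ds),
                branch_days = branch, branch_quantity = NA_character_)
}

#' @rdname cleaning
#' @export
clean_short_acting <- function(claims, config = study_config()) {
  assert_family(claims,
                claims$route == "injectable" & claims$formulation == "immediate",
                "short-acting injectable")
  q0 <- claims$cleaned_quantity
  uc <- claims$unit_cost
  tc <- claims$total_cost
  have_costs <- !is.na(uc) & !is.na(tc) & uc > 0 & tc > 0
  mismatch <- have_costs &
    abs(q0 * uc - tc) / tc > config$cost_mismatch_tolerance
  new_q <- ifelse(mismatch, round(tc / uc, 2), q0)
  res <- .oral_days_rule(claims, config, new_q)
  finish_family(claims, new_q = new_q, new_ds = res$ds,
                branch_days = res$branch,
                branch_quantity = ifelse(mismatch, "sa_quantity_repair",
                                         "sa_keep"))
}

finish_family <- function(claims, new_q, new_ds, branch_days, branch_quantity) {
  claims$cleaned_quantity <- new_q
  claims$cleaned_days_supply <- new_ds
  claims$quantity_modified <- abs(new_q - claims$quantity) > 1e-9
  claims$days_supply_modified <- new_ds != claims$days_supply
  attr(claims, "cleaning_branch") <-
    data.frame(claim_id = claims$claim_id, branch_days = branch_days,
               branch_quantity = branch_quantity, stringsAsFactors = FALSE)
  claims
}

#' @rdname cleaning
#' @export
clean_claims <- function(claims, intervals = default_interval_table(),
                         config = study_config()) {
  claims <- sort_claims(claims)
  validate_claims(claims)
  in_q <- claims$cleaned_quantity
  in_ds <- claims$cleaned_days_supply

  fam_oral <- claims$route %in% c("oral", "rectal")
  fam_la <- claims$route == "injectable" & claims$formulation == "long_acting"
  fam_sa <- claims$route == "injectable" & claims$formulation == "immediate"

  branch_days <- rep(NA_character_, nrow(claims))
  branch_quantity <- rep(NA_character_, nrow(claims))
  out <- claims

  apply_family <- function(mask, cleaned) {
    bi <- attr(cleaned, "cleaning_branch")
    out[mask, ] <<- cleaned[, names(out), drop = FALSE]
    branch_days[mask] <<- bi$branch_days
    branch_quantity[mask] <<- bi$branch_quantity
  }
  if (any(fam_oral)) {
    apply_family(fam_oral, clean_oral_rectal(claims[fam_oral, , drop = FALSE],
                                             config))
  }
  if (any(fam_la)) {
    apply_family(fam_la, clean_long_acting(claims[fam_la, , drop = FALSE],
                                           intervals, config))
  }
  if (any(fam_sa)) {
    apply_family(fam_sa, clean_short_acting(claims[fam_sa, , drop = FALSE],
                                            config))
  }

  q_mod_run <- abs(out$cleaned_quantity - in_q) > 1e-9
  ds_mod_run <- out$cleaned_days_supply != in_ds
  rule_applied <- mapply(function(qm, dm, bq, bd) {
    rules <- c(if (qm) bq, if (dm) bd)
    if (length(rules)) paste(rules, collapse = "+") else "none"
  }, q_mod_run, ds_mod_run, branch_quantity, branch_days, USE.NAMES = FALSE)

  report <- data.frame(
    claim_id = out$claim_id,
    patient_id = out$patient_id,
    route = out$route,
    formulation = out$formulation,
    branch_days = branch_days,
    branch_quantity = branch_quantity,
    raw_quantity = in_q,
    cleaned_quantity = out$cleaned_quantity,
    raw_days_supply = in_ds,
    cleaned_days_supply = out$cleaned_days_supply,
    quantity_modified = q_mod_run,
    days_supply_modified = ds_mod_run,
    rule_applied = rule_applied,
    stringsAsFactors = FALSE
  )
  validate_claims(out)
  list(claims = out, report = report)
}
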