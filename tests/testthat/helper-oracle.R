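# Independent brute-force re-derivations of the cleaning branches, cohort
# criteria, and eligibility decisions.  Deliberately naive (per-row loops,
# no shared helpers with the package) so they can serve as an oracle.

oracle_clean_one <- function(claims, i, intervals, config) {
  # returns list(quantity, days_supply) for claim i of a full claims table
  ci <- claims[i, ]
  mine <- claims[claims$patient_id == ci$patient_id, ]
  q <- ci$quantity
  ds <- ci$days_supply
  if (ci$route %in% c("oral", "rectal")) {
    fills <- mine[mine$route %in% c("oral", "rectal") & mine$drug == ci$drug &
                    mine$dispense_date > ci$dispense_date, ]
    gap <- if (nrow(fills)) min(as.numeric(fills$dispense_date - ci$dispense_date)) else Inf
    if (gap > config$next_fill_window_days) {
      ds <- max(1, floor(q / config$oral_fallback_divisor + 0.5))
    }
  } else if (ci$formulation == "long_acting") {
    m <- intervals$min_interval_days[intervals$drug == ci$drug]
    las <- mine[mine$formulation == "long_acting" &
                  mine$dispense_date > ci$dispense_date, ]
    gap <- if (nrow(las)) min(as.numeric(las$dispense_date - ci$dispense_date)) else NA
    if (ds > m) {
      # keep
    } else if (is.na(gap)) {
      ds <- m
    } else if (gap < m) {
      ds <- gap
    } else {
      ds <- m
    }
  } else {
    if (!is.na(ci$unit_cost) && !is.na(ci$total_cost) &&
        ci$unit_cost > 0 && ci$total_cost > 0 &&
        abs(q * ci$unit_cost - ci$total_cost) / ci$total_cost >
          config$cost_mismatch_tolerance) {
      q <- round(ci$total_cost / ci$unit_cost, 2)
    }
    fills <- mine[mine$route == "injectable" & mine$formulation == "immediate" &
                    mine$drug == ci$drug & mine$dispense_date > ci$dispense_date, ]
    gap <- if (nrow(fills)) min(as.numeric(fills$dispense_date - ci$dispense_date)) else Inf
    if (gap > config$next_fill_window_days) {
      ds <- max(1, floor(q / config$oral_fallback_divisor + 0.5))
    }
  }
  list(quantity = q, days_supply = as.integer(ds))
}

oracle_clean <- function(claims, intervals, config) {
  out <- claims
  for (i in seq_len(nrow(claims))) {
    res <- oracle_clean_one(claims, i, intervals, config)
    out$cleaned_quantity[i] <- res$quantity
    out$cleaned_days_supply[i] <- res$days_supply
  }
  out$quantity_modified <- abs(out$cleaned_quantity - out$quantity) > 1e-9
  out$days_supply_modified <- out$cleaned_days_supply != out$days_supply
  out
}

oracle_cohort <- function(patients, claims, config) {
  res <- list()
  for (p in patients$patient_id) {
    d <- claims$dispense_date[claims$patient_id == p]
    inw <- d[d >= config$accrual_start & d <= config$accrual_end]
    if (!length(inw)) next
    index <- min(inw)
    prow <- patients[patients$patient_id == p, ]
    reason <- "retained"
    if (!prow$dementia) {
      reason <- "no_dementia"
    } else if (oracle_age(prow$birth_date, index) < config$min_age_years) {
      reason <- "under_age"
    } else if (any(d > index - config$washout_days & d < index)) {
      reason <- "prior_use"
    } else if (!any(d > index & d <= index + config$followup_days)) {
      reason <- "no_subsequent_rx"
    }
    fe <- index + config$followup_days
    exit <- "end_of_study"
    if (!is.na(prow$death_date) && prow$death_date <= fe) {
      fe <- prow$death_date
      exit <- "death"
    }
    res[[p]] <- data.frame(patient_id = p, index_date = index, reason = reason,
                           followup_end = fe, exit_reason = exit,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

oracle_age <- function(birth, at) {
  a <- 0
  while (seq(as.Date(birth), by = "year", length.out = a + 2)[a + 2] <= at) {
    a <- a + 1
  }
  a
}

oracle_eligible_ids <- function(claims, index, tp, config, use_cleaned = TRUE) {
  ids <- character(0)
  for (i in seq_len(nrow(claims))) {
    d <- claims$dispense_date[i]
    ds <- if (use_cleaned) claims$cleaned_days_supply[i] else claims$days_supply[i]
    ok <- if (tp == 0) {
      d == index
    } else {
      t_date <- index + tp
      (d > t_date - config$lookback_days) && (d <= t_date) &&
        (t_date < d + ds)
    }
    if (ok) ids <- c(ids, claims$claim_id[i])
  }
  ids
}

# type-7 quantile by the textbook interpolation formula
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
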