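#' Generator configuration for synthetic claims
#'
#' The generator emulates the structure of provincial dispensing claims for
#' antipsychotics in an aged dementia cohort: a route mix dominated by oral
#' therapy, a minority of short-acting ("regular") and long-acting
#' injectables and multi-route initiators, concurrent (multi-drug) therapy
#' at initiation, refill streams with jittered gaps, discontinuation,
#' mortality, and — crucially — injected field errors of the kinds the
#' cleaning rules repair (a day's supply of 1 recorded for a one-time depot
#' injection; a dispensed quantity inconsistent with the billed costs; an
#' implausibly short oral day's supply).  Ground truth records every true
#' regimen value and every injected error, so recovery by the cleaning rules
#' can be measured exactly.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param accrual_start,accrual_end Accrual window for index dates.
#' @param route_mix Named probabilities for the initiating route class
#'   (`oral`, `regular_injectable`, `multiple`, `long_acting`); must sum
#'   to 1.
#' @param atypical_share Probability that the primary drug is atypical.
#' @param concurrency_prob Overall probability of concurrent (>= 2 distinct
#'   drugs) therapy at initiation.  Multi-route patients are concurrent by
#'   construction; the extra-drug probability for the others is derated so
#'   the overall rate equals this value.
#' @param error_probs Named per-route-class probabilities that a patient's
#'   index-date claim carries an injected field error.
#' @param refill_jitter Integer `c(lo, hi)` added uniformly to the day's
#'   supply to form oral refill gaps.
#' @param discontinuation_prob Per-refill probability of stopping therapy
#'   (drawn from the second fill onward).
#' @param mortality_1yr One-year mortality, applied as a constant hazard.
#' @param exclusion_fractions Named fractions of patients constructed to
#'   trigger each cohort exclusion (`no_dementia`, `under_age`, `prior_use`,
#'   `no_subsequent_rx`).
#' @param catalogue Drug catalogue (see [default_drug_catalogue()]).
#' @param intervals Minimum-dosing-interval table for long-acting drugs.
#' @return A validated `cpz_gen_config` list.
#' @export
generator_config <- function(n_patients = 1000L, seed = 1L,
                             accrual_start = as.Date("2009-01-01"),
                             accrual_end = as.Date("2012-12-31"),
                             route_mix = c(oral = 0.965,
                                           regular_injectable = 0.02,
                                           multiple = 0.01,
                                           long_acting = 0.005),
                             atypical_share = 0.81,
                             concurrency_prob = 0.14,
                             error_probs = c(oral = 0.03,
                                             regular_injectable = 0.16,
                                             long_acting = 0.36,
                                             multiple = 0.42),
                             refill_jitter = c(-3L, 7L),
                             discontinuation_prob = 0.06,
                             mortality_1yr = 0.20,
                             exclusion_fractions = c(no_dementia = 0.02,
                                                     under_age = 0.02,
                                                     prior_use = 0.02,
                                                     no_subsequent_rx = 0.02),
                             catalogue = default_drug_catalogue(),
                             intervals = default_interval_table()) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              accrual_start = as.Date(accrual_start),
              accrual_end = as.Date(accrual_end),
              route_mix = route_mix, atypical_share = atypical_share,
              concurrency_prob = concurrency_prob, error_probs = error_probs,
              refill_jitter = as.integer(refill_jitter),
              discontinuation_prob = discontinuation_prob,
              mortality_1yr = mortality_1yr,
              exclusion_fractions = exclusion_fractions,
              catalogue = catalogue, intervals = intervals)
  class(cfg) <- "cpz_gen_config"
  route_classes <- c("oral", "regular_injectable", "multiple", "long_acting")
  if (!setequal(names(cfg$route_mix), route_classes)) {
    stop("config error: route_mix must be named ",
         paste(route_classes, collapse = ", "), call. = FALSE)
  }
  cfg$route_mix <- cfg$route_mix[route_classes]
  if (!setequal(names(cfg$error_probs), route_classes)) {
    stop("config error: error_probs must be named ",
         paste(route_classes, collapse = ", "), call. = FALSE)
  }
  cfg$error_probs <- cfg$error_probs[route_classes]
  probs <- c(cfg$route_mix, cfg$error_probs, cfg$atypical_share,
             cfg$concurrency_prob, cfg$discontinuation_prob,
             cfg$mortality_1yr, cfg$exclusion_fractions)
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    stop("config error: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$route_mix) - 1) > 1e-9) {
    stop("config error: route_mix must sum to 1", call. = FALSE)
  }
  if (sum(cfg$exclusion_fractions) >= 1) {
    stop("config error: exclusion_fractions must sum to < 1", call. = FALSE)
  }
  if (cfg$n_patients < 1L) stop("config error: n_patients must be >= 1",
                                call. = FALSE)
  if (cfg$concurrency_prob < cfg$route_mix[["multiple"]]) {
    stop("config error: concurrency_prob cannot be below the multiple-route ",
         "share (multi-route patients are concurrent by construction)",
         call. = FALSE)
  }
  cfg
}

# fill dates (integer days) from start: repeated gaps, stopping at the
# horizon, at death, or by discontinuation from the min_fills-th fill onward
stream_dates <- function(start, gap_fun, horizon, death, disc_prob,
                         min_fills = 2L) {
  dates <- start
  repeat {
    if (length(dates) >= min_fills && stats::runif(1) < disc_prob) break
    nxt <- dates[length(dates)] + max(1L, gap_fun())
    if (nxt > horizon) break
    if (!is.na(death) && nxt >= death) break
    dates <- c(dates, nxt)
  }
  dates
}

#' Generate a synthetic claims cohort with ground truth
#'
#' @param config A [generator_config()] object.
#' @return A list:
#' \describe{
#'   \item{patients}{patient table (`patient_id`, `birth_date`,
#'     `death_date`, `dementia`).}
#'   \item{claims}{validated claims table, with injected errors applied.}
#'   \item{truth_claims}{per claim: `true_quantity`, `true_days_supply`,
#'     `error_injected` (`none`, `ds_too_short`, `ds_one_day_injection`,
#'     `quantity_cost_mismatch`).}
#'   \item{truth_patients}{per patient: designed `scenario`, `route_class`,
#'     `concurrent`, `error` flag, `index_date`.}
#' }
#' @export
simulate_claims <- function(config = generator_config()) {
  set.seed(config$seed)
  cat <- config$catalogue
  cat$drug <- canonical_drug(cat$drug)
  ivl <- config$intervals
  jit <- config$refill_jitter
  disc <- config$discontinuation_prob
  window_days <- as.integer(config$accrual_end - config$accrual_start)
  hazard <- -log(1 - config$mortality_1yr) / 365
  p_mult <- config$route_mix[["multiple"]]
  p_extra <- (config$concurrency_prob - p_mult) / (1 - p_mult)
  scen_names <- c("standard", names(config$exclusion_fractions))
  scen_probs <- c(1 - sum(config$exclusion_fractions),
                  config$exclusion_fractions)

  oral_rows <- which(cat$route == "oral")
  rectal_rows <- which(cat$route == "rectal")
  sa_rows <- which(cat$route == "injectable" & cat$formulation == "immediate")
  la_rows <- which(cat$route == "injectable" & cat$formulation == "long_acting")

  pick_class_row <- function(rows, exclude_drug = NULL) {
    if (!is.null(exclude_drug)) {
      rows <- rows[cat$drug[rows] != exclude_drug]
    }
    atyp <- stats::runif(1) < config$atypical_share
    sub <- rows[cat$class[rows] == if (atyp) "atypical" else "typical"]
    if (!length(sub)) sub <- rows
    sub[sample.int(length(sub), 1L)]
  }
  pick_oral <- function(exclude_drug = NULL) {
    if (length(rectal_rows) && stats::runif(1) < 0.02 &&
        !canonical_drug(cat$drug[rectal_rows[1]]) %in% exclude_drug) {
      return(rectal_rows[sample.int(length(rectal_rows), 1L)])
    }
    pick_class_row(oral_rows, exclude_drug)
  }

  pat <- list(patient_id = character(config$n_patients),
              birth = integer(config$n_patients),
              death = integer(config$n_patients),
              dementia = logical(config$n_patients))
  tpat <- list(scenario = character(config$n_patients),
               route_class = character(config$n_patients),
               concurrent = logical(config$n_patients),
               error = logical(config$n_patients),
               index = integer(config$n_patients))
  acc <- list()   # per-patient claim blocks
  targets <- character(0)
  claim_counter <- 0L

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    scenario <- scen_names[sample.int(length(scen_names), 1L,
                                      prob = scen_probs)]
    route_class <- names(config$route_mix)[
      sample.int(4L, 1L, prob = config$route_mix)]
    if (scenario == "no_subsequent_rx") route_class <- "long_acting"
    concurrent <- route_class == "multiple" ||
      (p_extra > 0 && stats::runif(1) < p_extra)
    error <- scenario == "standard" &&
      stats::runif(1) < config$error_probs[[route_class]]

    index <- as.integer(config$accrual_start) +
      if (scenario == "prior_use") sample(0:45, 1L) else
        sample.int(window_days + 1L, 1L) - 1L
    age <- if (scenario == "under_age") sample(64:65, 1L) else sample(70:92, 1L)
    birth <- as.integer(round(index - (age + stats::runif(1, 0.1, 0.9)) * 365.25))
    tdeath <- ceiling(stats::rexp(1, hazard))
    death <- if (tdeath <= 540) index + as.integer(tdeath) else NA_integer_
    horizon <- index + 465L

    rows <- list()  # each: list(row=catalogue row, dates, ds, qty, target)
    add_stream <- function(crow, dates, ds, qty, target_first = FALSE) {
      rows[[length(rows) + 1L]] <<- list(crow = crow, dates = dates, ds = ds,
                                         qty = qty, target = target_first)
    }
    oral_gap <- function(ds) function() ds + sample(jit[1]:jit[2], 1L)

    if (scenario == "no_subsequent_rx") {
      # a one-time depot injection, never refilled
      crow <- la_rows[sample.int(length(la_rows), 1L)]
      m <- ivl$min_interval_days[match(cat$drug[crow], ivl$drug)]
      add_stream(crow, index, ds = m, qty = sample(1:2, 1L))
    } else {
      inj_host <- NULL
      if (route_class %in% c("regular_injectable", "multiple") &&
          (route_class == "regular_injectable" || stats::runif(1) < 0.5)) {
        inj_host <- "sa"
      } else if (route_class %in% c("long_acting", "multiple")) {
        inj_host <- "la"
      }

      if (route_class == "oral" && error) {
        # erroneous first fill, then a switch to a different oral drug:
        # no same-drug refill, so the fallback day's-supply rule fires
        crow_a <- pick_oral()
        ds_a <- sample(c(30L, 60L, 90L), 1L, prob = c(0.6, 0.3, 0.1))
        add_stream(crow_a, index, ds_a, qty = 5 * ds_a, target_first = TRUE)
        crow_b <- pick_class_row(oral_rows, exclude_drug = cat$drug[crow_a])
        ds_b <- sample(c(30L, 60L), 1L)
        b_start <- index + sample(20:40, 1L)
        host_dates <-
          if (!is.na(death) && b_start >= death) integer(0) else
            stream_dates(b_start, oral_gap(ds_b), horizon, death, disc)
        if (length(host_dates)) {
          add_stream(crow_b, host_dates, ds_b, qty = 5 * ds_b)
        }
        host_for_partner <- c(index, host_dates)
      } else if (route_class == "oral") {
        crow_a <- pick_oral()
        ds_a <- sample(c(30L, 60L, 90L), 1L, prob = c(0.6, 0.3, 0.1))
        host_dates <- stream_dates(index, oral_gap(ds_a), horizon, death, disc)
        add_stream(crow_a, host_dates, ds_a, qty = 5 * ds_a,
                   target_first = error)
        host_for_partner <- host_dates
      } else if (inj_host == "sa") {
        crow_a <- pick_class_row(sa_rows)
        ds_a <- sample(c(7L, 14L), 1L)
        gap_fun <- function() ds_a + sample(0:5, 1L)
        host_dates <- stream_dates(index, gap_fun, horizon, death, disc)
        add_stream(crow_a, host_dates, ds_a, qty = 5 * ds_a,
                   target_first = error)
        host_for_partner <- host_dates
      } else {
        # long-acting host: injections at exactly the minimum dosing interval
        crow_a <- pick_class_row(la_rows)
        m <- ivl$min_interval_days[match(cat$drug[crow_a], ivl$drug)]
        host_dates <- stream_dates(index, function() m, horizon, death, disc)
        add_stream(crow_a, host_dates, ds = m, qty = sample(1:2, 1L),
                   target_first = error)
        host_for_partner <- host_dates
      }

      if (route_class == "multiple") {
        # oral co-therapy rides the injectable visit dates; a distinct drug,
        # so the multi-drug truth flag matches distinct-drug concurrency
        crow_o <- pick_oral(exclude_drug = cat$drug[rows[[1]]$crow])
        ds_o <- 30L
        add_stream(crow_o, host_for_partner, ds_o, qty = 5 * ds_o)
      }
      if (concurrent && route_class != "multiple") {
        if (route_class == "oral") {
          crow_c <- pick_oral(exclude_drug = cat$drug[rows[[1]]$crow])
          ds_c <- sample(c(30L, 60L), 1L)
          add_stream(crow_c, host_for_partner, ds_c, qty = 5 * ds_c)
        } else if (inj_host == "sa") {
          crow_c <- pick_class_row(sa_rows,
                                   exclude_drug = cat$drug[rows[[1]]$crow])
          add_stream(crow_c, host_for_partner, rows[[1]]$ds,
                     qty = 5 * rows[[1]]$ds)
        } else {
          # partner depot with interval <= the host's, dosed at host visits
          cand <- la_rows[cat$drug[la_rows] != cat$drug[rows[[1]]$crow]]
          m_c <- ivl$min_interval_days[match(cat$drug[cand], ivl$drug)]
          cand <- cand[m_c <= rows[[1]]$ds]
          crow_c <- cand[sample.int(length(cand), 1L)]
          add_stream(crow_c, host_for_partner,
                     ivl$min_interval_days[match(cat$drug[crow_c], ivl$drug)],
                     qty = 1L)
        }
      }
      if (scenario == "prior_use") {
        # a fill of the primary drug 60-100 days before the (in-window) index;
        # the gap stays inside the next-fill window so its day's supply keeps
        add_stream(rows[[1]]$crow, index - sample(60:100, 1L),
                   rows[[1]]$ds, rows[[1]]$qty)
      }
    }

    # materialize this patient's claim rows
    n_claims_i <- sum(vapply(rows, function(s) length(s$dates), integer(1)))
    if (n_claims_i > 0L) {
      blk <- list(claim_id = character(n_claims_i),
                  patient_id = rep(pid, n_claims_i),
                  drug = character(n_claims_i), route = character(n_claims_i),
                  formulation = character(n_claims_i),
                  strength_mg = numeric(n_claims_i),
                  quantity = numeric(n_claims_i),
                  days_supply = integer(n_claims_i),
                  dispense_date = integer(n_claims_i),
                  unit_cost = numeric(n_claims_i),
                  total_cost = numeric(n_claims_i))
      at <- 0L
      for (s in rows) {
        k <- length(s$dates)
        if (!k) next
        sel <- at + seq_len(k)
        ids <- sprintf("C%07d", claim_counter + seq_len(k))
        claim_counter <- claim_counter + k
        blk$claim_id[sel] <- ids
        blk$drug[sel] <- cat$drug[s$crow]
        blk$route[sel] <- cat$route[s$crow]
        blk$formulation[sel] <- cat$formulation[s$crow]
        blk$strength_mg[sel] <- cat$strength_mg[s$crow]
        blk$quantity[sel] <- s$qty
        blk$days_supply[sel] <- s$ds
        blk$dispense_date[sel] <- s$dates
        blk$unit_cost[sel] <- cat$unit_cost[s$crow]
        blk$total_cost[sel] <- round(s$qty * cat$unit_cost[s$crow], 2)
        if (s$target) {
          # the injected error targets the index-date claim of the stream
          targets <- c(targets, ids[which.min(s$dates)])
        }
        at <- at + k
      }
      acc[[length(acc) + 1L]] <- blk
    }

    pat$patient_id[i] <- pid
    pat$birth[i] <- birth
    pat$death[i] <- if (is.na(death)) NA_integer_ else death
    pat$dementia[i] <- scenario != "no_dementia"
    tpat$scenario[i] <- scenario
    tpat$route_class[i] <- route_class
    tpat$concurrent[i] <- concurrent
    tpat$error[i] <- error
    tpat$index[i] <- index
  }

  claims_df <- data.frame(
    claim_id = unlist(lapply(acc, `[[`, "claim_id")),
    patient_id = unlist(lapply(acc, `[[`, "patient_id")),
    drug = unlist(lapply(acc, `[[`, "drug")),
    route = unlist(lapply(acc, `[[`, "route")),
    formulation = unlist(lapply(acc, `[[`, "formulation")),
    strength_mg = unlist(lapply(acc, `[[`, "strength_mg")),
    quantity = unlist(lapply(acc, `[[`, "quantity")),
    days_supply = unlist(lapply(acc, `[[`, "days_supply")),
    dispense_date = as.Date(unlist(lapply(acc, `[[`, "dispense_date")),
                            origin = "1970-01-01"),
    unit_cost = unlist(lapply(acc, `[[`, "unit_cost")),
    total_cost = unlist(lapply(acc, `[[`, "total_cost")),
    stringsAsFactors = FALSE
  )
  claims <- as_claims(claims_df)
  patients <- as_patients(data.frame(
    patient_id = pat$patient_id,
    birth_date = as.Date(pat$birth, origin = "1970-01-01"),
    death_date = as.Date(pat$death, origin = "1970-01-01"),
    dementia = pat$dementia, stringsAsFactors = FALSE
  ))
  injected <- inject_errors(claims, targets, config)
  truth_claims <- data.frame(
    claim_id = claims$claim_id,
    patient_id = claims$patient_id,
    true_quantity = claims$quantity,
    true_days_supply = claims$days_supply,
    stringsAsFactors = FALSE
  )
  em <- match(truth_claims$claim_id, injected$errors$claim_id)
  truth_claims$error_injected <-
    ifelse(is.na(em), "none", injected$errors$error_injected[em])
  truth_patients <- data.frame(
    patient_id = pat$patient_id, scenario = tpat$scenario,
    route_class = tpat$route_class, concurrent = tpat$concurrent,
    error = tpat$error,
    index_date = as.Date(tpat$index, origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  list(patients = patients, claims = injected$claims,
       truth_claims = truth_claims, truth_patients = truth_patients)
}

#' Inject field errors into pristine claims
#'
#' Flips the raw fields of the targeted claims according to the archetype
#' matching each claim's route: long-acting injectables get a day's supply
#' of 1 recorded for the injection (`ds_one_day_injection`); short-acting
#' injectables get a dispensed quantity of 1 inconsistent with the billed
#' costs (`quantity_cost_mismatch`); oral and rectal claims get an
#' implausibly short day's supply (`ds_too_short`, 1-3 days).  Cleaned
#' fields are re-initialized to the flipped raw values.
#'
#' @param claims A validated claims table.
#' @param targets Character vector of claim ids to corrupt.
#' @param config A [generator_config()] (unused fields tolerated); present
#'   so alternative archetype parameterizations can hang off it.
#' @return `list(claims, errors)` where `errors` has one row per injected
#'   error (`claim_id`, `error_injected`).
#' @export
inject_errors <- function(claims, targets, config = generator_config()) {
  idx <- match(targets, claims$claim_id)
  if (anyNA(idx)) {
    stop("inject_errors: unknown claim id(s): ",
         paste(targets[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  kind <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (claims$formulation[i] == "long_acting") {
      claims$days_supply[i] <- 1L
      kind[k] <- "ds_one_day_injection"
    } else if (claims$route[i] == "injectable") {
      claims$quantity[i] <- 1
      kind[k] <- "quantity_cost_mismatch"
    } else {
      claims$days_supply[i] <- min(sample(1:3, 1L),
                                   max(1L, claims$days_supply[i] - 1L))
      kind[k] <- "ds_too_short"
    }
    claims$cleaned_quantity[i] <- claims$quantity[i]
    claims$cleaned_days_supply[i] <- claims$days_supply[i]
  }
  list(claims = claims,
       errors = data.frame(claim_id = targets, error_injected = kind,
                           stringsAsFactors = FALSE))
}

#' Reference exposure from ground-truth fields
#'
#' Rebuilds the claims with their true quantity and day's-supply values and
#' runs the same cohort and exposure operations.  Because error injection
#' never touches dispense dates, the truth cohort is identical to the
#' pipeline cohort, and the resulting assessments are the recovery target
#' for the cleaning rules.
#'
#' @param patients Patient table.
#' @param claims Claims table (with injected errors; only dates, drugs and
#'   strengths are used from it).
#' @param truth_claims Ground-truth table from [simulate_claims()].
#' @param table Equivalence table.
#' @param config A [study_config()] object.
#' @return Assessments computed from the true fields (see
#'   [assess_exposure()]).
#' @export
truth_exposure <- function(patients, claims, truth_claims,
                           table = default_equivalence_table(),
                           config = study_config()) {
  m <- match(claims$claim_id, truth_claims$claim_id)
  if (anyNA(m)) {
    stop("truth_exposure: claims and ground truth do not align", call. = FALSE)
  }
  true_claims <- claims
  true_claims$quantity <- truth_claims$true_quantity[m]
  true_claims$days_supply <- as.integer(truth_claims$true_days_supply[m])
  true_claims$cleaned_quantity <- true_claims$quantity
  true_claims$cleaned_days_supply <- true_claims$days_supply
  true_claims$quantity_modified <- FALSE
  true_claims$days_supply_modified <- FALSE
  cohort <- build_cohort(patients, true_claims, config)
  assess_exposure(cohort$members, true_claims, table, config)
}
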