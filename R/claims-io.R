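#' @keywords internal
"_PACKAGE"

CLAIM_COLUMNS <- c("claim_id", "patient_id", "drug", "route", "formulation",
                   "strength_mg", "quantity", "days_supply", "dispense_date",
                   "unit_cost", "total_cost")
ROUTES <- c("oral", "rectal", "injectable")
FORMULATIONS <- c("immediate", "long_acting")

#' Construct a validated claims table
#'
#' Normalizes a data frame of dispensing events into the canonical claims
#' representation: one row per dispensed prescription with canonical drug
#' tokens, typed columns, cleaned fields initialized to the raw values, and
#' rows sorted by (patient, dispense date, claim id).
#'
#' @param df A data frame with columns `claim_id`, `patient_id`, `drug`,
#'   `route` (oral/rectal/injectable), `formulation` (immediate/long_acting),
#'   `strength_mg` (mg of ingredient per dispensed unit), `quantity`
#'   (dispensed units), `days_supply` (integer days), `dispense_date`
#'   (ISO-8601), and optionally `unit_cost` / `total_cost` (may be missing).
#' @return The claims data frame, validated, with `cleaned_quantity`,
#'   `cleaned_days_supply`, `quantity_modified`, `days_supply_modified`
#'   columns appended (flags all `FALSE`).
#' @export
as_claims <- function(df) {
  required <- setdiff(CLAIM_COLUMNS, c("unit_cost", "total_cost"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing required claim column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  claims <- data.frame(
    claim_id = as.character(df$claim_id),
    patient_id = as.character(df$patient_id),
    drug = canonical_drug(df$drug),
    route = as.character(df$route),
    formulation = as.character(df$formulation),
    strength_mg = as.numeric(df$strength_mg),
    quantity = as.numeric(df$quantity),
    days_supply = as.integer(df$days_supply),
    dispense_date = as.Date(df$dispense_date),
    unit_cost = if ("unit_cost" %in% names(df)) as.numeric(df$unit_cost) else NA_real_,
    total_cost = if ("total_cost" %in% names(df)) as.numeric(df$total_cost) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (all(c("cleaned_quantity", "cleaned_days_supply", "quantity_modified",
            "days_supply_modified") %in% names(df))) {
    # round-tripping an already-cleaned table: keep the cleaned fields
    claims$cleaned_quantity <- as.numeric(df$cleaned_quantity)
    claims$cleaned_days_supply <- as.integer(df$cleaned_days_supply)
    claims$quantity_modified <- as_flag(df$quantity_modified)
    claims$days_supply_modified <- as_flag(df$days_supply_modified)
  } else {
    claims$cleaned_quantity <- claims$quantity
    claims$cleaned_days_supply <- claims$days_supply
    claims$quantity_modified <- FALSE
    claims$days_supply_modified <- FALSE
  }
  validate_claims(claims)
  sort_claims(claims)
}

sort_claims <- function(claims) {
  ord <- order(claims$patient_id, claims$dispense_date, claims$claim_id)
  claims <- claims[ord, , drop = FALSE]
  rownames(claims) <- NULL
  claims
}

is_sorted_claims <- function(claims) {
  ord <- order(claims$patient_id, claims$dispense_date, claims$claim_id)
  identical(ord, seq_len(nrow(claims)))
}

#' Validate claim-level invariants
#'
#' Checks every row of a claims table against the type invariants and fails
#' with a message naming the offending claim ids and fields.
#'
#' @param claims A claims data frame (raw columns; cleaned columns optional).
#' @return The claims table, invisibly, if valid.
#' @export
validate_claims <- function(claims) {
  problems <- character(0)
  flag <- function(bad, field, why) {
    if (any(bad)) {
      ids <- claims$claim_id[bad]
      problems <<- c(problems, sprintf(
        "claim %s: field %s %s", utils::head(ids, 10), field, why))
    }
  }
  flag(is.na(claims$claim_id) | claims$claim_id == "", "claim_id", "is missing")
  flag(is.na(claims$patient_id) | claims$patient_id == "", "patient_id", "is missing")
  flag(is.na(claims$drug) | claims$drug == "", "drug", "is missing")
  flag(!claims$route %in% ROUTES, "route",
       sprintf("must be one of {%s}", paste(ROUTES, collapse = ", ")))
  flag(!claims$formulation %in% FORMULATIONS, "formulation",
       sprintf("must be one of {%s}", paste(FORMULATIONS, collapse = ", ")))
  flag(claims$formulation == "long_acting" & claims$route != "injectable" &
         claims$route %in% ROUTES,
       "formulation", "long_acting is valid only with route=injectable")
  flag(!is.finite(claims$strength_mg) | claims$strength_mg <= 0,
       "strength_mg", "must be > 0")
  flag(!is.finite(claims$quantity) | claims$quantity <= 0,
       "quantity", "must be > 0")
  flag(is.na(claims$days_supply) | claims$days_supply < 1L,
       "days_supply", "must be an integer >= 1")
  flag(is.na(claims$dispense_date), "dispense_date", "must be a valid date")
  flag(!is.na(claims$unit_cost) & claims$unit_cost < 0, "unit_cost", "must be >= 0")
  flag(!is.na(claims$total_cost) & claims$total_cost < 0, "total_cost", "must be >= 0")
  if ("cleaned_days_supply" %in% names(claims)) {
    flag(is.na(claims$cleaned_days_supply) | claims$cleaned_days_supply < 1L,
         "cleaned_days_supply", "must be an integer >= 1")
    flag(!is.finite(claims$cleaned_quantity) | claims$cleaned_quantity <= 0,
         "cleaned_quantity", "must be > 0")
    flag(!claims$quantity_modified &
           abs(claims$cleaned_quantity - claims$quantity) > 1e-9,
         "cleaned_quantity", "differs from quantity but quantity_modified is FALSE")
    flag(!claims$days_supply_modified &
           claims$cleaned_days_supply != claims$days_supply,
         "cleaned_days_supply",
         "differs from days_supply but days_supply_modified is FALSE")
  }
  if (length(problems)) {
    stop("claims validation failed:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "), call. = FALSE)
  }
  invisible(claims)
}

#' Read dispensing claims from a delimited text file
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(drug = "DIN_NAME")`; columns
#'   not mentioned are taken verbatim.
#' @return A validated claims data frame (see [as_claims()]).
#' @export
read_claims <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop("schema error: mapped column not found in file: ", src,
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  as_claims(df)
}

#' Read the patient table
#'
#' @param path CSV with columns `patient_id`, `birth_date`, `death_date`
#'   (may be empty), `dementia` (TRUE/FALSE or 1/0).
#' @return A validated patients data frame.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_patients(df)
}

#' Construct a validated patient table
#' @param df Data frame with `patient_id`, `birth_date`, `death_date`, `dementia`.
#' @return A validated patients data frame.
#' @export
as_patients <- function(df) {
  required <- c("patient_id", "birth_date", "dementia")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing required patient column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dd <- if ("death_date" %in% names(df)) {
    x <- as.character(df$death_date)
    x[!is.na(x) & x == ""] <- NA
    as.Date(x)
  } else {
    as.Date(rep(NA_character_, nrow(df)))
  }
  dementia_raw <- df$dementia
  dementia <- if (is.logical(dementia_raw)) dementia_raw else {
    tolower(as.character(dementia_raw)) %in% c("true", "t", "1", "yes")
  }
  patients <- data.frame(
    patient_id = as.character(df$patient_id),
    birth_date = as.Date(df$birth_date),
    death_date = dd,
    dementia = dementia,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(patients$patient_id)) {
    stop("patients validation failed: duplicated patient_id", call. = FALSE)
  }
  bad <- !is.na(patients$death_date) & patients$death_date < patients$birth_date
  if (any(bad)) {
    stop("patients validation failed: death_date before birth_date for ",
         paste(utils::head(patients$patient_id[bad], 10), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(patients$birth_date))) {
    stop("patients validation failed: invalid birth_date for ",
         paste(utils::head(patients$patient_id[is.na(patients$birth_date)], 10),
               collapse = ", "), call. = FALSE)
  }
  rownames(patients) <- NULL
  patients[order(patients$patient_id), , drop = FALSE]
}

#' Read a dose-equivalence table
#'
#' The table maps each (drug, formulation) pair to its chlorpromazine
#' conversion factor: mg of chlorpromazine-equivalent per mg of drug per day.
#' The identity entry (chlorpromazine, immediate) = 1.0 must be present.
#'
#' @param path CSV (columns `drug`, `formulation`, `cpz_factor`) or YAML file
#'   (a list of entries with those fields).
#' @return A validated equivalence data frame.
#' @export
read_equivalence_table <- function(path) {
  df <- read_table_csv_or_yaml(path, c("drug", "formulation", "cpz_factor"))
  as_equivalence_table(df)
}

#' Construct a validated dose-equivalence table
#' @param df Data frame with `drug`, `formulation`, `cpz_factor`.
#' @return Validated equivalence data frame with canonical drug tokens.
#' @export
as_equivalence_table <- function(df) {
  tab <- data.frame(
    drug = canonical_drug(df$drug),
    formulation = as.character(df$formulation),
    cpz_factor = as.numeric(df$cpz_factor),
    stringsAsFactors = FALSE
  )
  if (any(!tab$formulation %in% FORMULATIONS)) {
    stop("config error: equivalence table formulation must be one of {",
         paste(FORMULATIONS, collapse = ", "), "}", call. = FALSE)
  }
  if (any(!is.finite(tab$cpz_factor) | tab$cpz_factor <= 0)) {
    stop("config error: equivalence factors must be > 0 (offending drugs: ",
         paste(tab$drug[!is.finite(tab$cpz_factor) | tab$cpz_factor <= 0],
               collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(paste(tab$drug, tab$formulation))) {
    stop("config error: duplicated (drug, formulation) in equivalence table",
         call. = FALSE)
  }
  idx <- tab$drug == "chlorpromazine" & tab$formulation == "immediate"
  if (!any(idx) || tab$cpz_factor[idx] != 1.0) {
    stop("config error: equivalence table must contain the identity entry ",
         "(chlorpromazine, immediate) with cpz_factor = 1.0", call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Look up chlorpromazine conversion factors
#'
#' @param table An equivalence table (see [read_equivalence_table()]).
#' @param drug,formulation Character vectors (recycled to a common length).
#' @return Numeric vector of factors; unmapped pairs raise an error naming
#'   every unmapped drug encountered.
#' @export
cpz_factor <- function(table, drug, formulation) {
  key <- paste(canonical_drug(drug), formulation, sep = "\r")
  tab_key <- paste(table$drug, table$formulation, sep = "\r")
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    miss <- unique(paste0(canonical_drug(drug)[is.na(idx)], " (",
                          formulation[is.na(idx)], ")"))
    stop("unmapped drug(s) in equivalence table: ",
         paste(sort(miss), collapse = ", "), call. = FALSE)
  }
  table$cpz_factor[idx]
}

#' Read a minimum-dosing-interval table for long-acting injectables
#'
#' @param path CSV (columns `drug`, `min_interval_days`) or YAML file.
#' @return Validated interval data frame.
#' @export
read_interval_table <- function(path) {
  df <- read_table_csv_or_yaml(path, c("drug", "min_interval_days"))
  as_interval_table(df)
}

#' Construct a validated dosing-interval table
#' @param df Data frame with `drug`, `min_interval_days`.
#' @return Validated interval data frame with canonical drug tokens.
#' @export
as_interval_table <- function(df) {
  tab <- data.frame(
    drug = canonical_drug(df$drug),
    min_interval_days = as.integer(df$min_interval_days),
    stringsAsFactors = FALSE
  )
  if (any(is.na(tab$min_interval_days) | tab$min_interval_days < 1L)) {
    stop("config error: min_interval_days must be an integer >= 1",
         call. = FALSE)
  }
  if (anyDuplicated(tab$drug)) {
    stop("config error: duplicated drug in interval table", call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

read_table_csv_or_yaml <- function(path, required) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("yml", "yaml")) {
    entries <- yaml::read_yaml(path)
    do.call(rbind, lapply(entries, function(e) as.data.frame(e, stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("config error: table at ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write and read back exposure assessments
#'
#' One row per (patient, timepoint): route class, raw and cleaned total
#' chlorpromazine-equivalent daily dose, contributing-claim count and ids.
#' The round trip through CSV is lossless for integer/date/id fields and
#' preserves doses to well below 1e-9 mg.
#'
#' @param assessments Assessments as produced by [assess_exposure()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(assessments, path) {
  out <- assessments
  for (col in c("total_cpz_mg_raw", "total_cpz_mg_cleaned")) {
    out[[col]] <- format_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_exposure_table
#' @export
read_exposure_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  df$modified_by_cleaning <- as.logical(df$modified_by_cleaning)
  df$contributing_claim_ids <- as.character(df$contributing_claim_ids)
  df$route_class <- as.character(df$route_class)
  df
}

as_flag <- function(x) {
  if (is.logical(x)) x else tolower(as.character(x)) %in% c("true", "t", "1")
}

# full-precision, locale-independent numeric formatting for CSV output
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE,
                                            trim = TRUE)
  }, character(1))
  out
}
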