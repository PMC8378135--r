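#' Run the full dose-conversion study
#'
#' One call that chains the pipeline on in-memory tables: clean the claims,
#' build the new-user cohort, assess chlorpromazine-equivalent exposure at
#' every configured timepoint, and summarize by route and timepoint.
#'
#' @param claims Claims table from [read_claims()] / [as_claims()].
#' @param patients Patient table.
#' @param equivalence Dose-equivalence table
#'   (default [default_equivalence_table()]).
#' @param intervals Minimum-dosing-interval table
#'   (default [default_interval_table()]).
#' @param config A [study_config()] object.
#' @return An object of class `cpz_study`: a list with `claims` (cleaned),
#'   `report` (per-claim cleaning report), `members`, `exclusions`,
#'   `assessments`, `summary` (`by_route`, `by_timepoint`), and the three
#'   configuration tables.  Has `print`, `summary`, and `plot` methods.
#' @examples
#' sim <- simulate_claims(generator_config(n_patients = 200, seed = 42))
#' fit <- run_study(sim$claims, sim$patients)
#' fit
#' summary(fit)
#' @export
run_study <- function(claims, patients,
                      equivalence = default_equivalence_table(),
                      intervals = default_interval_table(),
                      config = study_config()) {
  cleaned <- clean_claims(claims, intervals, config)
  cohort <- build_cohort(patients, cleaned$claims, config)
  assessments <- assess_exposure(cohort$members, cleaned$claims, equivalence,
                                 config)
  res <- list(claims = cleaned$claims, report = cleaned$report,
              members = cohort$members, exclusions = cohort$exclusions,
              assessments = assessments,
              summary = summarize_exposure(assessments),
              equivalence = equivalence, intervals = intervals,
              config = config)
  class(res) <- "cpz_study"
  res
}

#' @export
print.cpz_study <- function(x, ...) {
  excl <- table(x$exclusions$reason)
  cat("Chlorpromazine-equivalent dose-conversion study (cpz_study)\n")
  cat(sprintf("  claims: %d (%d modified by cleaning)\n", nrow(x$claims),
              sum(x$claims$quantity_modified | x$claims$days_supply_modified)))
  cat(sprintf("  candidates: %d; cohort: %d retained\n",
              nrow(x$exclusions), nrow(x$members)))
  for (r in setdiff(names(excl), "retained")) {
    cat(sprintf("    excluded %-16s %d\n", paste0(r, ":"), excl[[r]]))
  }
  tp <- x$summary$by_timepoint
  for (k in seq_len(nrow(tp))) {
    cat(sprintf("  day %3d: %d on therapy, %.1f%% concurrent\n",
                tp$timepoint_days[k], tp$n_active[k], tp$pct_concurrent[k]))
  }
  invisible(x)
}

#' @export
summary.cpz_study <- function(object, ...) {
  out <- object$summary
  out$by_route$pct_modified <- round(out$by_route$pct_modified, 1)
  out$by_timepoint$pct_concurrent <- round(out$by_timepoint$pct_concurrent, 1)
  out$by_timepoint$pct_multi_claim <- round(out$by_timepoint$pct_multi_claim, 1)
  class(out) <- "summary.cpz_study"
  out
}

#' @export
print.summary.cpz_study <- function(x, ...) {
  cat("Median total CPZ-equivalent daily dose (mg) by route and timepoint:\n")
  print(x$by_route, row.names = FALSE)
  cat("\nPer-timepoint persistence and concurrency:\n")
  print(x$by_timepoint, row.names = FALSE)
  invisible(x)
}

#' Box-and-whisker plot of the dose distribution at a timepoint
#'
#' Raw-field and cleaned-field total equivalent daily doses side by side per
#' route stratum, with 1.5 x IQR whiskers and outliers.
#'
#' @param x A `cpz_study` object.
#' @param timepoint_days Timepoint to plot (default 0, initiation).
#' @param log Use a log dose axis (default `TRUE`).
#' @param ... Passed to [graphics::bxp()].
#' @return The plot-data table, invisibly.
#' @export
plot.cpz_study <- function(x, timepoint_days = 0L, log = TRUE, ...) {
  pd <- dose_plot_data(x$assessments, timepoint_days)
  stats_mat <- t(as.matrix(pd[, c("whisker_lo", "q1", "median", "q3",
                                  "whisker_hi")]))
  out <- lapply(strsplit(pd$outliers, ";", fixed = TRUE), as.numeric)
  bx <- list(stats = stats_mat, n = pd$n,
             conf = matrix(NA_real_, 2, nrow(pd)),
             out = unlist(out),
             group = rep(seq_len(nrow(pd)),
                         vapply(out, length, integer(1))),
             names = paste(abbreviate(pd$route_class, 8), pd$fields))
  graphics::bxp(bx, log = if (log) "y" else "",
                ylab = "total CPZ-equivalent daily dose (mg/day)",
                main = sprintf("Dose distribution at day %d", timepoint_days),
                las = 2, ...)
  invisible(pd)
}

#' Run the pipeline end to end on files
#'
#' Executes (optionally) simulate, then clean, cohort, exposure, and
#' summarize, writing every stage output as CSV plus a JSON run manifest
#' with the configuration snapshot, seed, input digests, per-stage row
#' counts, and package version.  Re-running with the same inputs and seed
#' reproduces byte-identical outputs.
#'
#' @param output_dir Directory for stage outputs (created if needed).
#' @param claims_path,patients_path Input CSVs (ignored when `simulate`).
#' @param simulate Generate inputs with [simulate_claims()] instead of
#'   reading files.
#' @param gen_config Generator configuration used when `simulate = TRUE`.
#' @param equivalence,intervals,config As in [run_study()].
#' @return The `cpz_study` object, invisibly, with the manifest attached as
#'   attribute `manifest`.
#' @export
run_all <- function(output_dir, claims_path = NULL, patients_path = NULL,
                    simulate = FALSE, gen_config = generator_config(),
                    equivalence = default_equivalence_table(),
                    intervals = default_interval_table(),
                    config = study_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  digests <- character(0)
  if (simulate) {
    sim <- simulate_claims(gen_config)
    claims <- sim$claims
    patients <- sim$patients
    write_csv_stable(sim$truth_claims, file.path(output_dir, "truth_claims.csv"))
    write_csv_stable(sim$truth_patients,
                     file.path(output_dir, "truth_patients.csv"))
    write_claims_csv(claims, file.path(output_dir, "claims_raw.csv"))
    write_csv_stable(patients, file.path(output_dir, "patients.csv"))
  } else {
    if (is.null(claims_path) || is.null(patients_path)) {
      stop("config error: claims_path and patients_path are required unless ",
           "simulate = TRUE", call. = FALSE)
    }
    claims <- read_claims(claims_path)
    patients <- read_patients(patients_path)
    digests <- tools::md5sum(c(claims_path, patients_path))
  }
  fit <- run_study(claims, patients, equivalence, intervals, config)

  write_claims_csv(fit$claims, file.path(output_dir, "claims_clean.csv"))
  write_csv_stable(fit$report, file.path(output_dir, "cleaning_report.csv"))
  write_csv_stable(fit$members, file.path(output_dir, "cohort.csv"))
  write_csv_stable(fit$exclusions, file.path(output_dir, "exclusions.csv"))
  write_exposure_table(fit$assessments, file.path(output_dir, "exposure.csv"))
  sum_route <- fit$summary$by_route
  sum_route$pct_modified <- round(sum_route$pct_modified, 1)
  sum_tp <- fit$summary$by_timepoint
  sum_tp$pct_concurrent <- round(sum_tp$pct_concurrent, 1)
  sum_tp$pct_multi_claim <- round(sum_tp$pct_multi_claim, 1)
  write_csv_stable(sum_route, file.path(output_dir, "summary_by_route.csv"))
  write_csv_stable(sum_tp, file.path(output_dir, "summary_by_timepoint.csv"))
  for (tp in config$timepoints_days) {
    write_csv_stable(dose_plot_data(fit$assessments, tp),
                     file.path(output_dir, sprintf("plot_data_day%03d.csv", tp)))
  }

  manifest <- list(
    tool = "cpzequiv",
    version = as.character(utils::packageVersion("cpzequiv")),
    seed = if (simulate) gen_config$seed else NA,
    simulate = simulate,
    config = manifest_config(config),
    input_digests = as.list(digests),
    row_counts = list(claims = nrow(fit$claims),
                      patients = nrow(patients),
                      candidates = nrow(fit$exclusions),
                      cohort = nrow(fit$members),
                      assessments = nrow(fit$assessments))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  attr(fit, "manifest") <- manifest
  invisible(fit)
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$accrual_start <- as.character(cfg$accrual_start)
  cfg$accrual_end <- as.character(cfg$accrual_end)
  cfg
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

write_claims_csv <- function(claims, path) {
  out <- claims
  for (col in c("strength_mg", "quantity", "unit_cost", "total_cost",
                "cleaned_quantity")) {
    out[[col]] <- format_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
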