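#' Median equivalent dose by route and timepoint
#'
#' Per (timepoint, route class) stratum of the assessments: patient count,
#' median, and quartiles (type-7 linear interpolation) of the cleaned total
#' chlorpromazine-equivalent daily dose.  Empty strata are absent rows, not
#' zeros.
#'
#' @param assessments Assessments from [assess_exposure()].
#' @return Data frame `timepoint_days`, `route_class`, `n`, `q1`, `median`,
#'   `q3`.
#' @export
median_dose_by_route <- function(assessments) {
  strata <- split(assessments$total_cpz_mg_cleaned,
                  list(assessments$timepoint_days, assessments$route_class),
                  drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(strata), "\r", fixed = TRUE))
  qs <- t(vapply(strata, stats::quantile, numeric(3),
                 probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  out <- data.frame(
    timepoint_days = as.integer(keys[, 1]),
    route_class = keys[, 2],
    n = vapply(strata, length, integer(1)),
    q1 = qs[, 1], median = qs[, 2], q3 = qs[, 3],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$timepoint_days, out$route_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of patients whose total dose was modified by cleaning
#'
#' Per (timepoint, route class) stratum: `100 * #modified / n`, where a
#' patient counts as modified when the cleaned-field and raw-field totals
#' differ by more than the configured tolerance (a field change whose effect
#' cancels out does not count).
#'
#' @param assessments Assessments from [assess_exposure()].
#' @return Data frame `timepoint_days`, `route_class`, `n`, `pct_modified`.
#' @export
percent_modified <- function(assessments) {
  strata <- split(assessments$modified_by_cleaning,
                  list(assessments$timepoint_days, assessments$route_class),
                  drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(strata), "\r", fixed = TRUE))
  out <- data.frame(
    timepoint_days = as.integer(keys[, 1]),
    route_class = keys[, 2],
    n = vapply(strata, length, integer(1)),
    pct_modified = 100 * vapply(strata, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$timepoint_days, out$route_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of patients on concurrent (multiple-drug) therapy
#'
#' Per timepoint: percentage of assessed patients with two or more distinct
#' drugs contributing exposure (distinct drugs, not distinct claims: two
#' fills of the same drug are one therapy).
#'
#' @param assessments Assessments from [assess_exposure()].
#' @return Data frame `timepoint_days`, `n`, `pct_concurrent`.
#' @export
percent_concurrent <- function(assessments) {
  tps <- split(assessments$n_drugs, assessments$timepoint_days)
  out <- data.frame(
    timepoint_days = as.integer(names(tps)),
    n = vapply(tps, length, integer(1)),
    pct_concurrent = 100 * vapply(tps, function(x) mean(x >= 2), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$timepoint_days), , drop = FALSE]
}

#' Boxplot data for the dose distribution at a timepoint
#'
#' Per route stratum and field set (raw vs cleaned): type-7 quartiles,
#' whiskers extending to the most extreme data point within 1.5 x IQR of the
#' box edges, and the outliers beyond them.
#'
#' @param assessments Assessments from [assess_exposure()].
#' @param timepoint_days The timepoint to plot.
#' @return Data frame `route_class`, `fields` (raw/cleaned), `n`,
#'   `whisker_lo`, `q1`, `median`, `q3`, `whisker_hi`, `outliers`
#'   (";"-separated values).
#' @export
dose_plot_data <- function(assessments, timepoint_days = 0L) {
  a <- assessments[assessments$timepoint_days == timepoint_days, , drop = FALSE]
  rows <- list()
  for (route in sort(unique(a$route_class))) {
    for (fields in c("raw", "cleaned")) {
      x <- if (fields == "raw") a$total_cpz_mg_raw else a$total_cpz_mg_cleaned
      x <- x[a$route_class == route]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[3] + 1.5 * iqr
      inside <- x >= lo_fence & x <= hi_fence
      rows[[length(rows) + 1L]] <- data.frame(
        route_class = route, fields = fields, n = length(x),
        whisker_lo = min(x[inside]), q1 = q[1], median = q[2], q3 = q[3],
        whisker_hi = max(x[inside]),
        outliers = paste(format_num(sort(x[!inside])), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full summary table
#'
#' Combines [median_dose_by_route()] and [percent_modified()] into one
#' stratified table, plus a per-timepoint table with the active-patient
#' count, the concurrency percentage, and the percentage with more than one
#' contributing claim.
#'
#' @param assessments Assessments from [assess_exposure()].
#' @return `list(by_route, by_timepoint)`.
#' @export
summarize_exposure <- function(assessments) {
  if (nrow(assessments) == 0L) {
    return(list(
      by_route = data.frame(timepoint_days = integer(0),
                            route_class = character(0), n = integer(0),
                            q1 = numeric(0), median = numeric(0),
                            q3 = numeric(0), pct_modified = numeric(0)),
      by_timepoint = data.frame(timepoint_days = integer(0),
                                n_active = integer(0),
                                pct_concurrent = numeric(0),
                                pct_multi_claim = numeric(0))))
  }
  med <- median_dose_by_route(assessments)
  pm <- percent_modified(assessments)
  by_route <- merge(med, pm[, c("timepoint_days", "route_class", "pct_modified")],
                    by = c("timepoint_days", "route_class"), sort = TRUE)
  pc <- percent_concurrent(assessments)
  tps <- split(assessments$n_claims, assessments$timepoint_days)
  by_timepoint <- data.frame(
    timepoint_days = as.integer(names(tps)),
    n_active = vapply(tps, length, integer(1)),
    pct_concurrent = pc$pct_concurrent[match(as.integer(names(tps)),
                                             pc$timepoint_days)],
    pct_multi_claim = 100 * vapply(tps, function(x) mean(x > 1), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(by_timepoint) <- NULL
  list(by_route = by_route, by_timepoint = by_timepoint)
}
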