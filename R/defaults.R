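#' Bundled default dose-equivalence table
#'
#' Conversion factors give mg of chlorpromazine-equivalent per mg of drug per
#' day, anchored at 100 mg/day of oral chlorpromazine (e.g. risperidone 2 mg
#' ~ chlorpromazine 100 mg, hence factor 50).  Immediate-release factors are
#' reconstructed from published relative-potency equivalence work on
#' antipsychotics; depot (long-acting) factors are per-mg-of-depot-per-day
#' reconstructions and are rougher.  These defaults are a starting point, not
#' a validated reference: replace them with a jurisdiction- and
#' study-specific table via [read_equivalence_table()] for production use.
#'
#' @return A validated equivalence data frame
#'   (`drug`, `formulation`, `cpz_factor`).
#' @export
default_equivalence_table <- function() {
  tab <- data.frame(
    drug = c("chlorpromazine", "haloperidol", "fluphenazine", "perphenazine",
             "loxapine", "risperidone", "olanzapine", "quetiapine",
             "aripiprazole", "clozapine", "ziprasidone",
             "haloperidol decanoate", "fluphenazine decanoate",
             "risperidone microspheres", "zuclopenthixol decanoate"),
    formulation = c(rep("immediate", 11), rep("long_acting", 4)),
    cpz_factor = c(1, 50, 50, 12.5,
                   10, 50, 20, 100 / 75,
                   100 / 7.5, 2, 100 / 60,
                   70, 110,
                   56, 4),
    stringsAsFactors = FALSE
  )
  as_equivalence_table(tab)
}

#' Bundled default minimum-dosing-interval table
#'
#' Minimum recommended interval, in days, between administrations of each
#' long-acting injectable (e.g. 28 days for haloperidol decanoate).  Used by
#' the long-acting day's-supply cleaning rule; every long-acting drug in the
#' claims must have an entry.
#'
#' @return A validated interval data frame (`drug`, `min_interval_days`).
#' @export
default_interval_table <- function() {
  as_interval_table(data.frame(
    drug = c("haloperidol decanoate", "fluphenazine decanoate",
             "risperidone microspheres", "zuclopenthixol decanoate"),
    min_interval_days = c(28L, 14L, 14L, 14L),
    stringsAsFactors = FALSE
  ))
}

#' Bundled drug catalogue for the synthetic claims generator
#'
#' A small product list spanning routes, formulations, and typical/atypical
#' classes, with plausible per-unit strengths (mg per tablet, or mg per mL
#' for injectables) and unit costs.  Entirely synthetic and replaceable via
#' [generator_config()]; it does not reproduce any specific formulary.
#'
#' @return Data frame with columns `drug`, `route`, `formulation`, `class`
#'   (typical/atypical), `strength_mg`, `unit_cost`.
#' @export
default_drug_catalogue <- function() {
  rows <- list(
    # oral atypicals
    c("risperidone", "oral", "immediate", "atypical", 0.5, 0.45),
    c("risperidone", "oral", "immediate", "atypical", 1, 0.75),
    c("risperidone", "oral", "immediate", "atypical", 2, 1.10),
    c("olanzapine", "oral", "immediate", "atypical", 2.5, 1.20),
    c("olanzapine", "oral", "immediate", "atypical", 5, 1.90),
    c("olanzapine", "oral", "immediate", "atypical", 10, 3.10),
    c("quetiapine", "oral", "immediate", "atypical", 25, 0.55),
    c("quetiapine", "oral", "immediate", "atypical", 100, 1.40),
    c("quetiapine", "oral", "immediate", "atypical", 200, 2.20),
    c("aripiprazole", "oral", "immediate", "atypical", 5, 2.60),
    c("aripiprazole", "oral", "immediate", "atypical", 10, 3.40),
    # oral typicals
    c("haloperidol", "oral", "immediate", "typical", 0.5, 0.12),
    c("haloperidol", "oral", "immediate", "typical", 1, 0.16),
    c("haloperidol", "oral", "immediate", "typical", 2, 0.24),
    c("loxapine", "oral", "immediate", "typical", 5, 0.30),
    c("loxapine", "oral", "immediate", "typical", 10, 0.45),
    c("chlorpromazine", "oral", "immediate", "typical", 25, 0.18),
    c("chlorpromazine", "oral", "immediate", "typical", 50, 0.25),
    c("perphenazine", "oral", "immediate", "typical", 4, 0.22),
    # rectal
    c("chlorpromazine", "rectal", "immediate", "typical", 100, 1.60),
    # short-acting injectables (strength per mL)
    c("haloperidol", "injectable", "immediate", "typical", 5, 3.50),
    c("loxapine", "injectable", "immediate", "typical", 25, 4.25),
    c("olanzapine", "injectable", "immediate", "atypical", 5, 9.00),
    # long-acting injectables (strength per mL)
    c("haloperidol decanoate", "injectable", "long_acting", "typical", 100, 12.00),
    c("fluphenazine decanoate", "injectable", "long_acting", "typical", 25, 8.50),
    c("risperidone microspheres", "injectable", "long_acting", "atypical", 12.5, 85.00),
    c("zuclopenthixol decanoate", "injectable", "long_acting", "typical", 200, 10.00)
  )
  cat <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(cat) <- c("drug", "route", "formulation", "class", "strength_mg",
                  "unit_cost")
  cat$strength_mg <- as.numeric(cat$strength_mg)
  cat$unit_cost <- as.numeric(cat$unit_cost)
  cat
}
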