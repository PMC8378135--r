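TAB <- default_equivalence_table()

test_that("daily dose spreads the dispensed mass over the supply period", {
  claims <- make_claims(claim_row("C1", strength_mg = 2.5, quantity = 60,
                                  days_supply = 30))
  expect_equal(daily_dose_mg(claims), 5.0)
  # depot: 100 mg/mL, 1 mL over a cleaned 28-day supply
  la <- clean_claims(make_claims(
    claim_row("C1", drug = "haloperidol decanoate", route = "injectable",
              formulation = "long_acting", strength_mg = 100, quantity = 1,
              days_supply = 1)))$claims
  expect_equal(la$cleaned_days_supply, 28L)
  expect_equal(daily_dose_mg(la, use_cleaned = TRUE), 100 / 28)
  # raw fields keep the 1-day supply: raw dose = 28 x cleaned dose
  expect_equal(daily_dose_mg(la, use_cleaned = FALSE),
               28 * daily_dose_mg(la, use_cleaned = TRUE))
})

test_that("chlorpromazine equivalents multiply by the conversion factor", {
  cpz <- make_claims(claim_row("C1", drug = "chlorpromazine",
                               strength_mg = 100, quantity = 30,
                               days_supply = 30))
  expect_equal(cpz_equivalent_mg(cpz, TAB), 100.0)  # identity factor
  risp <- make_claims(claim_row("C2", drug = "risperidone", strength_mg = 1,
                                quantity = 60, days_supply = 30))
  expect_equal(cpz_equivalent_mg(risp, TAB), 100.0)  # 2 mg/day x 50
  unmapped <- make_claims(claim_row("C3", drug = "brexpiprazole"))
  expect_error(cpz_equivalent_mg(unmapped, TAB), "brexpiprazole")
})

elig_case <- function(offset_days, ds, index = as.Date("2010-01-01"),
                      tp = 182L, use_cleaned = TRUE) {
  claims <- clean_claims(make_claims(
    claim_row("C1", quantity = 5 * ds, days_supply = ds,
              dispense_date = as.character(index + tp + offset_days)),
    claim_row("C2", quantity = 5 * ds, days_supply = ds,
              dispense_date = as.character(index + tp + offset_days + 10))
  ))$claims
  nrow(eligible_claims(claims[1, ], index, tp, cfg0, use_cleaned)) == 1L
}

test_that("eligibility needs the lookback window and timepoint coverage", {
  expect_true(elig_case(-10, 30))    # dispensed t-10, covers t
  expect_false(elig_case(-120, 200)) # outside the 100-day lookback
  expect_false(elig_case(-10, 5))    # coverage ended before t
  # half-open conventions
  expect_true(elig_case(0, 1))       # dispensed on t with >= 1 day supply
  expect_false(elig_case(-30, 30))   # dispense + ds == t: no longer covers
  expect_false(elig_case(-100, 200)) # dispensed exactly t-100: window is open
  expect_true(elig_case(-99, 200))
})

test_that("initiation eligibility is same-day claims only", {
  index <- as.Date("2010-01-01")
  claims <- clean_claims(make_claims(
    claim_row("C1", dispense_date = "2010-01-01", quantity = 300,
              days_supply = 60),
    claim_row("C2", dispense_date = "2010-01-02", quantity = 300,
              days_supply = 60, drug = "olanzapine"),
    claim_row("C3", dispense_date = "2010-01-30", quantity = 300,
              days_supply = 60)
  ))$claims
  elig <- eligible_claims(claims, index, 0L, cfg0)
  expect_equal(elig$claim_id, "C1")
})

test_that("route classification folds rectal into oral and detects mixes", {
  oral2 <- make_claims(claim_row("C1"), claim_row("C2", drug = "olanzapine",
                                                  dispense_date = "2010-01-01"))
  expect_equal(classify_route(oral2), "oral")
  rect <- make_claims(claim_row("C1", route = "rectal",
                                drug = "chlorpromazine", strength_mg = 100))
  expect_equal(classify_route(rect), "oral")
  sa <- make_claims(claim_row("C1", route = "injectable",
                              formulation = "immediate", drug = "haloperidol",
                              strength_mg = 5))
  expect_equal(classify_route(sa), "regular_injectable")
  la <- make_claims(claim_row("C1", drug = "haloperidol decanoate",
                              route = "injectable",
                              formulation = "long_acting", strength_mg = 100,
                              quantity = 1, days_supply = 28))
  expect_equal(classify_route(la), "long_acting_injectable")
  expect_equal(classify_route(rbind(oral2, la)), "multiple")
  expect_error(classify_route(oral2[0, ]), "non-empty")
})

test_that("assessments sum equivalents over eligible claims", {
  claims <- clean_claims(make_claims(
    claim_row("C1", drug = "chlorpromazine", strength_mg = 100, quantity = 30,
              days_supply = 30, dispense_date = "2010-06-01"),
    claim_row("C2", drug = "risperidone", strength_mg = 0.5, quantity = 60,
              days_supply = 30, dispense_date = "2010-06-01"),
    claim_row("C3", drug = "chlorpromazine", strength_mg = 100, quantity = 30,
              days_supply = 30, dispense_date = "2010-06-20"),
    claim_row("C4", drug = "risperidone", strength_mg = 0.5, quantity = 60,
              days_supply = 30, dispense_date = "2010-06-21")
  ))$claims
  members <- build_cohort(make_patients(patient_row("P1")), claims,
                          cfg0)$members
  a <- assess_exposure(members, claims, TAB, cfg0)
  a0 <- a[a$timepoint_days == 0, ]
  # 100 mg/day CPZ + 1 mg/day risperidone x 50 = 150
  expect_equal(a0$total_cpz_mg_cleaned, 150.0)
  expect_equal(a0$n_claims, 2L)
  expect_equal(a0$n_drugs, 2L)
  expect_equal(a0$route_class, "oral")
  # nothing covers day 182: no assessment row at all
  expect_false(182L %in% a$timepoint_days)
})

test_that("totals modified by cleaning are proportional for a single claim", {
  claims <- clean_claims(make_claims(
    claim_row("C1", drug = "haloperidol decanoate", route = "injectable",
              formulation = "long_acting", strength_mg = 100, quantity = 1,
              days_supply = 1, dispense_date = "2010-06-01"),
    claim_row("C2", drug = "haloperidol decanoate", route = "injectable",
              formulation = "long_acting", strength_mg = 100, quantity = 1,
              days_supply = 28, dispense_date = "2010-06-29")
  ))$claims
  members <- build_cohort(make_patients(patient_row("P1")), claims,
                          cfg0)$members
  a0 <- assess_exposure(members, claims, TAB, cfg0, timepoints_days = 0L)
  expect_true(a0$modified_by_cleaning)
  expect_equal(a0$total_cpz_mg_raw, 28 * a0$total_cpz_mg_cleaned)
})

test_that("a chlorpromazine-only cohort has total equal to the daily dose", {
  claims <- clean_claims(make_claims(
    claim_row("C1", drug = "chlorpromazine", strength_mg = 25, quantity = 90,
              days_supply = 30, dispense_date = "2010-06-01"),
    claim_row("C2", drug = "chlorpromazine", strength_mg = 25, quantity = 90,
              days_supply = 30, dispense_date = "2010-06-29")
  ))$claims
  members <- build_cohort(make_patients(patient_row("P1")), claims,
                          cfg0)$members
  a0 <- assess_exposure(members, claims, TAB, cfg0, timepoints_days = 0L)
  expect_equal(a0$total_cpz_mg_cleaned, daily_dose_mg(claims[1, ]))
})

test_that("totals are additive, permutation-invariant, and scale-equivariant", {
  sim <- simulate_claims(generator_config(n_patients = 120, seed = 31))
  fit <- run_study(sim$claims, sim$patients)
  a <- fit$assessments
  # additivity: recompute each total from the contributing claims
  for (i in sample(nrow(a), min(nrow(a), 200))) {
    ids <- strsplit(a$contributing_claim_ids[i], ";", fixed = TRUE)[[1]]
    sub <- fit$claims[match(ids, fit$claims$claim_id), ]
    expect_equal(sum(cpz_equivalent_mg(sub, TAB)), a$total_cpz_mg_cleaned[i])
  }
  # permutation invariance: shuffle claim rows before the pipeline
  set.seed(99)
  shuffled <- sim$claims[sample(nrow(sim$claims)), ]
  fit2 <- run_study(shuffled, sim$patients)
  expect_equal(fit2$assessments, a)
  # scale equivariance: scaling every strength scales every total
  scaled <- sim$claims
  scaled$strength_mg <- scaled$strength_mg * 3
  fit3 <- run_study(scaled, sim$patients)
  expect_equal(fit3$assessments$total_cpz_mg_cleaned,
               3 * a$total_cpz_mg_cleaned)
  expect_equal(fit3$assessments$total_cpz_mg_raw, 3 * a$total_cpz_mg_raw)
})

test_that("eligible_claims matches the brute-force oracle on random claims", {
  set.seed(404)
  index <- as.Date("2010-01-01")
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    claims <- clean_claims(as_claims(do.call(rbind, lapply(seq_len(n),
      function(i) {
        claim_row(sprintf("C%02d", i),
                  quantity = sample(c(30, 150, 300), 1),
                  days_supply = sample(c(5, 30, 60, 100), 1),
                  dispense_date = as.character(index + sample(0:400, 1)))
      }))))$claims
    for (tp in c(0L, 182L, 365L)) {
      for (uc in c(TRUE, FALSE)) {
        got <- eligible_claims(claims, index, tp, cfg0, uc)$claim_id
        want <- oracle_eligible_ids(claims, index, tp, cfg0, uc)
        expect_equal(got, want)
      }
    }
  }
})
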