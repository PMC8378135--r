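D0 <- as.Date("2010-03-01")

test_that("oral rule keeps the day's supply when a same-drug refill is near", {
  claims <- make_claims(
    claim_row("C1", quantity = 60, days_supply = 30,
              dispense_date = as.character(D0)),
    claim_row("C2", quantity = 60, days_supply = 30,
              dispense_date = as.character(D0 + 28))
  )
  res <- clean_claims(claims)
  c1 <- res$claims[res$claims$claim_id == "C1", ]
  expect_equal(c1$cleaned_days_supply, 30L)
  expect_false(c1$days_supply_modified)
  expect_equal(res$report$branch_days[res$report$claim_id == "C1"],
               "oral_keep")
})

test_that("oral fallback divides the quantity by 5 when no refill follows", {
  claims <- make_claims(claim_row("C1", quantity = 60, days_supply = 30))
  res <- clean_claims(claims)
  expect_equal(res$claims$cleaned_days_supply, 12L)  # 60 / 5
  expect_true(res$claims$days_supply_modified)
  expect_equal(res$report$rule_applied, "oral_fallback")
})

test_that("oral fallback fires when the next refill is beyond the window", {
  claims <- make_claims(
    claim_row("C1", quantity = 100, days_supply = 100,
              dispense_date = as.character(D0)),
    claim_row("C2", quantity = 100, days_supply = 100,
              dispense_date = as.character(D0 + 150))
  )
  res <- clean_claims(claims)
  c1 <- res$claims[res$claims$claim_id == "C1", ]
  expect_equal(c1$cleaned_days_supply, 20L)  # 150 > 100-day window; 100 / 5
  expect_true(c1$days_supply_modified)
})

test_that("the 100-day refill window is inclusive and same-drug only", {
  at_100 <- make_claims(
    claim_row("C1", quantity = 90, days_supply = 90,
              dispense_date = as.character(D0)),
    claim_row("C2", quantity = 90, days_supply = 90,
              dispense_date = as.character(D0 + 100))
  )
  res <- clean_claims(at_100)
  expect_false(res$claims$days_supply_modified[
    res$claims$claim_id == "C1"])
  other_drug <- make_claims(
    claim_row("C1", drug = "risperidone", quantity = 60, days_supply = 30,
              dispense_date = as.character(D0)),
    claim_row("C2", drug = "olanzapine", quantity = 60, days_supply = 30,
              dispense_date = as.character(D0 + 28))
  )
  res2 <- clean_claims(other_drug)
  expect_true(res2$claims$days_supply_modified[
    res2$claims$claim_id == "C1"])
  # same drug, different strength still matches
  diff_strength <- make_claims(
    claim_row("C1", strength_mg = 1, quantity = 60, days_supply = 30,
              dispense_date = as.character(D0)),
    claim_row("C2", strength_mg = 2, quantity = 60, days_supply = 30,
              dispense_date = as.character(D0 + 28))
  )
  res3 <- clean_claims(diff_strength)
  expect_false(res3$claims$days_supply_modified[
    res3$claims$claim_id == "C1"])
})

test_that("fallback day's supply rounds half-up and floors at one day", {
  for (case in list(c(q = 2, ds_exp = 1),     # 0.4 -> 0 -> floored to 1
                    c(q = 12, ds_exp = 2),    # 2.4 -> 2
                    c(q = 13, ds_exp = 3),    # 2.6 -> 3
                    c(q = 12.5, ds_exp = 3))) {  # 2.5 rounds half-up
    claims <- make_claims(claim_row("C1", quantity = case[["q"]],
                                    days_supply = 99))
    res <- clean_claims(claims)
    expect_equal(res$claims$cleaned_days_supply, as.integer(case[["ds_exp"]]))
  }
})

la_claim <- function(id, ds, date, drug = "haloperidol decanoate") {
  claim_row(id, drug = drug, route = "injectable",
            formulation = "long_acting", strength_mg = 100, quantity = 1,
            days_supply = ds, dispense_date = as.character(date))
}

test_that("long-acting day's supply above the minimum interval is kept", {
  res <- clean_claims(make_claims(la_claim("C1", 30, D0)))
  expect_equal(res$claims$cleaned_days_supply, 30L)  # 30 > 28
  expect_false(res$claims$days_supply_modified)
})

test_that("long-acting with no subsequent injection gets the minimum interval", {
  res <- clean_claims(make_claims(la_claim("C1", 1, D0)))
  expect_equal(res$claims$cleaned_days_supply, 28L)
  expect_true(res$claims$days_supply_modified)
  expect_equal(res$report$rule_applied, "la_set_min_interval")
})

test_that("long-acting uses the gap when the next injection comes early", {
  res <- clean_claims(make_claims(la_claim("C1", 28, D0),
                                  la_claim("C2", 28, D0 + 21)))
  c1 <- res$claims[res$claims$claim_id == "C1", ]
  expect_equal(c1$cleaned_days_supply, 21L)  # 28 not > 28, and 21 < 28
  expect_equal(res$report$branch_days[res$report$claim_id == "C1"],
               "la_set_gap")
})

test_that("long-acting with a late next injection gets the minimum interval", {
  res <- clean_claims(make_claims(la_claim("C1", 14, D0),
                                  la_claim("C2", 28, D0 + 60)))
  c1 <- res$claims[res$claims$claim_id == "C1", ]
  expect_equal(c1$cleaned_days_supply, 28L)
})

test_that("the long-acting gap search matches any long-acting drug", {
  res <- clean_claims(make_claims(
    la_claim("C1", 28, D0),
    la_claim("C2", 14, D0 + 21, drug = "fluphenazine decanoate")))
  c1 <- res$claims[res$claims$claim_id == "C1", ]
  expect_equal(c1$cleaned_days_supply, 21L)
})

test_that("a long-acting drug without an interval entry is a config error", {
  claims <- make_claims(la_claim("C1", 28, D0, drug = "newdepot"))
  expect_error(clean_claims(claims), "newdepot")
})

sa_claim <- function(id, qty, uc, tc, date = D0, ds = 2,
                     drug = "haloperidol") {
  claim_row(id, drug = drug, route = "injectable", formulation = "immediate",
            strength_mg = 5, quantity = qty, days_supply = ds,
            dispense_date = as.character(date), unit_cost = uc,
            total_cost = tc)
}

test_that("short-acting quantity is repaired from the billed costs", {
  res <- clean_claims(make_claims(sa_claim("C1", 1, 2.50, 25.00)))
  expect_equal(res$claims$cleaned_quantity, 10.0)  # 25.00 / 2.50
  expect_true(res$claims$quantity_modified)
  expect_equal(res$report$branch_quantity, "sa_quantity_repair")
})

test_that("cost-consistent short-acting quantities are untouched", {
  res <- clean_claims(make_claims(sa_claim("C1", 10, 2.50, 25.00)))
  expect_equal(res$claims$cleaned_quantity, 10)
  expect_false(res$claims$quantity_modified)
  expect_equal(res$report$branch_quantity, "sa_keep")
})

test_that("the repaired quantity feeds the day's-supply fallback", {
  res <- clean_claims(make_claims(sa_claim("C1", 1, 2.50, 25.00, ds = 7)))
  expect_equal(res$claims$cleaned_days_supply, 2L)  # round(10 / 5)
  expect_equal(res$report$rule_applied, "sa_quantity_repair+oral_fallback")
})

test_that("missing costs leave the short-acting quantity untouched", {
  res <- clean_claims(make_claims(sa_claim("C1", 3, NA, NA, ds = 1)))
  expect_equal(res$claims$cleaned_quantity, 3)
  expect_equal(res$report$branch_quantity, "sa_keep")
})

test_that("repaired quantities reproduce the billed cost within rounding", {
  set.seed(77)
  for (k in 1:50) {
    qty_true <- round(runif(1, 1, 40), 2)
    uc <- round(runif(1, 0.5, 20), 2)
    tc <- round(qty_true * uc, 2)
    res <- clean_claims(make_claims(sa_claim("C1", 1, uc, tc)))
    q2 <- res$claims$cleaned_quantity
    expect_lte(abs(q2 * uc - tc), 0.005 * uc + 1e-9)
  }
})

test_that("clean_claims dispatches each claim to exactly one rule family", {
  claims <- make_claims(
    claim_row("C1", dispense_date = as.character(D0)),
    claim_row("C2", route = "rectal", drug = "chlorpromazine",
              strength_mg = 100, dispense_date = as.character(D0)),
    la_claim("C3", 1, D0),
    sa_claim("C4", 1, 2.5, 25, D0),
    claim_row("C5", dispense_date = as.character(D0 + 28)),
    la_claim("C6", 30, D0 + 28)
  )
  res <- clean_claims(claims)
  rep <- res$report
  expect_true(all(grepl("^oral", rep$branch_days[rep$route %in% c("oral", "rectal")])))
  expect_true(all(grepl("^la", rep$branch_days[rep$formulation == "long_acting"])))
  expect_true(all(!is.na(rep$branch_quantity[
    rep$route == "injectable" & rep$formulation == "immediate"])))
})

test_that("cleaning is idempotent and a second pass reports nothing", {
  sim <- simulate_claims(generator_config(n_patients = 150, seed = 5))
  first <- clean_claims(sim$claims)
  second <- clean_claims(first$claims)
  expect_identical(second$claims, first$claims)
  expect_true(all(second$report$rule_applied == "none"))
})

test_that("cleaning never alters identity, dates, strength, or costs", {
  sim <- simulate_claims(generator_config(n_patients = 100, seed = 6))
  res <- clean_claims(sim$claims)
  frozen <- c("claim_id", "patient_id", "drug", "route", "formulation",
              "strength_mg", "dispense_date", "unit_cost", "total_cost",
              "quantity", "days_supply")
  expect_identical(res$claims[frozen], resort_claims(sim$claims)[frozen])
})

test_that("report flags are consistent with the rule_applied summary", {
  sim <- simulate_claims(generator_config(n_patients = 200, seed = 9))
  rep <- clean_claims(sim$claims)$report
  none <- rep$rule_applied == "none"
  expect_identical(none, !(rep$quantity_modified | rep$days_supply_modified))
})

test_that("family cleaners enforce their contracts", {
  oral <- make_claims(claim_row("C1"))
  la <- make_claims(la_claim("C2", 28, D0))
  expect_error(clean_oral_rectal(la), "contract error")
  expect_error(clean_long_acting(oral), "contract error")
  expect_error(clean_short_acting(oral), "contract error")
  unsorted <- rbind(make_claims(claim_row("C2", dispense_date = "2010-05-01"),
                                claim_row("C1"))[2:1, ])
  expect_error(clean_oral_rectal(unsorted), "sorted")
})

test_that("oral branch membership matches a brute-force re-derivation", {
  set.seed(123)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    dates <- as.character(D0 + sort(sample(0:300, n, replace = TRUE)))
    drugs <- sample(c("risperidone", "olanzapine"), n, replace = TRUE)
    claims <- as_claims(do.call(rbind, lapply(seq_len(n), function(i) {
      claim_row(sprintf("C%02d", i), drug = drugs[i],
                quantity = sample(c(30, 60, 90), 1),
                days_supply = sample(c(10, 30, 60), 1),
                dispense_date = dates[i])
    })))
    got <- clean_claims(claims)$claims
    want <- oracle_clean(claims, default_interval_table(), cfg0)
    expect_equal(got$cleaned_days_supply, want$cleaned_days_supply)
    expect_equal(got$days_supply_modified, want$days_supply_modified)
  }
})
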