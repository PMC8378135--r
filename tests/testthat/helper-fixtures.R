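# in-code fixtures: quick constructors for claims and patients

claim_row <- function(claim_id = "C1", patient_id = "P1", drug = "risperidone",
                      route = "oral", formulation = "immediate",
                      strength_mg = 1, quantity = 60, days_supply = 30,
                      dispense_date = "2010-01-01", unit_cost = NA,
                      total_cost = NA) {
  data.frame(claim_id = claim_id, patient_id = patient_id, drug = drug,
             route = route, formulation = formulation,
             strength_mg = strength_mg, quantity = quantity,
             days_supply = days_supply, dispense_date = dispense_date,
             unit_cost = unit_cost, total_cost = total_cost,
             stringsAsFactors = FALSE)
}

make_claims <- function(...) {
  as_claims(do.call(rbind, list(...)))
}

patient_row <- function(patient_id = "P1", birth_date = "1935-06-15",
                        death_date = NA, dementia = TRUE) {
  data.frame(patient_id = patient_id, birth_date = birth_date,
             death_date = death_date, dementia = dementia,
             stringsAsFactors = FALSE)
}

make_patients <- function(...) {
  as_patients(do.call(rbind, list(...)))
}

# default config used throughout the fixtures: 2010-01-01 index dates fall
# inside the default accrual window, so tests mostly use the defaults
cfg0 <- study_config()

resort_claims <- function(claims) {
  claims <- claims[order(claims$patient_id, claims$dispense_date,
                         claims$claim_id), , drop = FALSE]
  rownames(claims) <- NULL
  claims
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
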