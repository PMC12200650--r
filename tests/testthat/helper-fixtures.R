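# Shared in-code fixtures for the test suite.

# minimal product table: one weak short-acting, one strong, one excluded,
# one long-acting transdermal product
tiny_products <- function() {
  data.frame(
    product_id = c("COD", "MOR", "MET", "BUP-TD", "BUP-SL"),
    product_name = c("codeine", "morphine", "methadone",
                     "transdermal buprenorphine",
                     "sublingual buprenorphine"),
    strength_mg = c(30, 10, 5, 0.24, 2),
    mme_factor = c(0.1, 1.0, 4.7, 75, 30),
    potency_class = c("weak", "strong", "strong", "strong", "strong"),
    action_class = c("short-acting", "short-acting", "long-acting",
                     "long-acting", "short-acting"),
    excluded_flag = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    typical_daily_units = c(8, 2, 1, 1, 1),
    typical_supply_days = c(28, 28, 28, 28, 28),
    stringsAsFactors = FALSE
  )
}

# raw prescription rows, defaulting to complete plausible fields
raw_rx <- function(patient_id, issue_date, product_id = "COD",
                   quantity = 224, daily_dose_units = 8,
                   duration_days = NA_integer_) {
  data.frame(patient_id = patient_id,
             issue_date = as.Date(issue_date),
             product_id = product_id,
             quantity = quantity,
             daily_dose_units = daily_dose_units,
             duration_days = duration_days,
             stringsAsFactors = FALSE)
}

# clean prescriptions straight from day offsets relative to an index date
clean_rx_from_offsets <- function(patient_id, index_date, issue_offsets,
                                  supply_days,
                                  potency = "weak",
                                  action = "short-acting") {
  index_date <- as.Date(index_date)
  start <- index_date + issue_offsets
  data.frame(patient_id = patient_id,
             product_id = "COD",
             supply_start = start,
             supply_days = as.integer(supply_days),
             supply_end = start + supply_days - 1,
             daily_mme = 24,
             potency_class = potency,
             action_class = action,
             imputed_quantity = FALSE,
             imputed_daily_dose = FALSE,
             stringsAsFactors = FALSE)
}

# single-patient register row
one_patient <- function(patient_id = "P1", birth_year = 1960,
                        registration_start = "2000-01-01",
                        registration_end = "2025-12-31",
                        death_date = NA,
                        last_collection_date = "2025-12-31") {
  data.frame(patient_id = patient_id, sex = "F",
             birth_year = as.integer(birth_year),
             registration_start = as.Date(registration_start),
             registration_end = as.Date(registration_end),
             death_date = as.Date(death_date),
             last_collection_date = as.Date(last_collection_date),
             region = "London", imd_quintile = 3L,
             ethnicity = "White", smoking = "Never", drinking = "Never",
             stringsAsFactors = FALSE)
}

dx <- function(patient_id, date, category) {
  data.frame(patient_id = patient_id, date = as.Date(date),
             category = category, stringsAsFactors = FALSE)
}

# one index event row as build_cohort would emit
index_event <- function(patient_id = "P1", index_date = "2010-06-01") {
  index_date <- as.Date(index_date)
  data.frame(patient_id = patient_id, index_date = index_date,
             index_year = as.integer(format(index_date, "%Y")),
             stringsAsFactors = FALSE)
}

# random small phenotyping instance on day offsets, for oracle comparison;
# offsets and supplies straddle every rule boundary (window edges, 90-day
# span, 90 covered days)
random_instance <- function() {
  k <- sample(0:10, 1)
  if (k == 0) {
    return(list(issue_d = integer(0), supply = integer(0)))
  }
  issue_d <- sort(sample(0:500, k))
  supply <- sample(1:90, k, replace = TRUE)
  list(issue_d = issue_d, supply = supply)
}

run_detector_on_instance <- function(inst, index_date = as.Date("2012-03-01")) {
  ev <- index_event("PX", index_date)
  if (length(inst$issue_d) == 0) {
    rx <- clean_rx_from_offsets("PX", index_date, 0, 1)[0, ]
    # detect_ltot needs at least the patient split; give an unrelated patient
    rx <- clean_rx_from_offsets("PY", index_date, 0, 1)
  } else {
    rx <- clean_rx_from_offsets("PX", index_date, inst$issue_d, inst$supply)
  }
  detect_ltot(ev, rx)
}

oracle_on_instance <- function(inst) {
  brute_force_ltot(inst$issue_d, inst$issue_d,
                   inst$issue_d + inst$supply - 1L)
}
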