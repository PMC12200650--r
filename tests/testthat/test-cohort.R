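study_start <- as.Date("2009-01-01")
study_end <- as.Date("2019-12-31")

test_that("washout rule admits issues with a clean 365-day lookback", {
  pats <- one_patient("P1", registration_start = "2000-01-01")
  rx <- clean_rx_from_offsets("P1", "2009-02-15", c(0L, 379L), c(7L, 7L))
  ev <- find_incident_index_dates(rx, pats, study_start, study_end)
  # both issues qualify: the first has a clean lookback within registration,
  # the second follows a >365-day gap
  expect_equal(ev$index_date, as.Date(c("2009-02-15", "2010-03-01")))

  rx2 <- clean_rx_from_offsets("P1", "2009-06-01", c(0L, 273L), c(7L, 7L))
  ev2 <- find_incident_index_dates(rx2, pats, study_start, study_end)
  expect_equal(ev2$index_date, as.Date("2009-06-01"))  # 2010-03-01 too close
})

test_that("registration lookback and age at index gate eligibility", {
  pats <- rbind(one_patient("P1", registration_start = "2009-06-01"),
                one_patient("P2", birth_year = 1995,
                            registration_start = "2000-01-01"))
  pats$patient_id <- c("P1", "P2")
  # P1: first-ever issue 100 days after registration -> insufficient lookback
  # P2: aged 17 in 2012 -> too young; aged 18 in 2013 -> eligible
  rx <- rbind(
    clean_rx_from_offsets("P1", as.Date("2009-06-01") + 100, 0L, 7L),
    clean_rx_from_offsets("P2", "2012-05-01", 0L, 7L),
    clean_rx_from_offsets("P2", "2013-06-01", 0L, 7L))
  ev <- find_incident_index_dates(rx, pats, study_start, study_end)
  expect_equal(ev$patient_id, "P2")
  expect_equal(ev$index_date, as.Date("2013-06-01"))
})

test_that("chronic-pain inclusion and ten-year cancer exclusion", {
  ev <- rbind(index_event("A", "2012-01-01"), index_event("B", "2012-01-01"),
              index_event("C", "2012-01-01"), index_event("D", "2012-01-01"),
              index_event("E", "2012-01-01"))
  diagnoses <- rbind(
    dx("A", as.Date("2012-01-01") + 150, "CNCP"),   # within 183 d after
    dx("B", as.Date("2012-01-01") + 200, "CNCP"),   # too late
    dx("C", "2011-01-01", "CNCP"),
    dx("C", as.Date("2012-01-01") - 9 * 365, "cancer"),  # within 10 y
    dx("D", "2011-01-01", "CNCP"),
    dx("D", "2010-01-01", "NMSC"),                  # NMSC never excludes
    dx("E", "2011-01-01", "CNCP"),
    dx("E", as.Date("2012-01-01") - 3651, "cancer")  # outside 10 y window
  )
  kept <- apply_cncp_and_cancer_rules(ev, diagnoses)
  expect_setequal(kept$patient_id, c("A", "D", "E"))
})

test_that("follow-up ends at the earliest censoring event with its reason", {
  ev <- index_event("P1", "2012-01-01")
  diagnoses <- dx("P1", "2014-01-01", "CNCP")[0, ]

  pats <- one_patient("P1", death_date = "2015-01-01")
  out <- compute_followup_end(ev, pats, diagnoses, study_end)
  expect_equal(out$followup_end, as.Date("2015-01-01"))
  expect_equal(out$censor_reason, "death")

  pats2 <- one_patient("P1")
  out2 <- compute_followup_end(ev, pats2, diagnoses, study_end)
  expect_equal(out2$followup_end, study_end)
  expect_equal(out2$censor_reason, "study_end")

  dx_cancer <- dx("P1", as.Date("2012-01-01") + 730, "cancer")
  out3 <- compute_followup_end(ev, pats2, dx_cancer, study_end)
  expect_equal(out3$followup_end, as.Date("2012-01-01") + 730)
  expect_equal(out3$censor_reason, "cancer")

  pats4 <- one_patient("P1", registration_end = "2013-05-05")
  out4 <- compute_followup_end(ev, pats4, diagnoses, study_end)
  expect_equal(out4$censor_reason, "transfer")
})

test_that("every retained event passes a brute-force eligibility re-check", {
  ds <- generate_dataset(sim_config(n_patients = 400, seed = 77))
  clean <- prepare_prescriptions(ds$prescriptions, ds$config$formulary)
  ev <- build_cohort(clean, ds$patients, ds$diagnoses,
                     study_start, study_end)
  expect_gt(nrow(ev), 50)
  issues_by_pat <- split(clean$supply_start, clean$patient_id)
  for (k in seq_len(nrow(ev))) {
    pid <- ev$patient_id[k]
    idx <- ev$index_date[k]
    p <- ds$patients[ds$patients$patient_id == pid, ]
    d <- ds$diagnoses[ds$diagnoses$patient_id == pid, ]
    iss <- issues_by_pat[[pid]]
    expect_equal(sum(iss >= idx - 365 & iss < idx), 0)
    expect_gte(as.integer(idx - p$registration_start), 365)
    expect_gte(ev$index_year[k] - p$birth_year, 18)
    expect_true(any(d$category == "CNCP" & d$date <= idx + 183))
    expect_false(any(d$category == "cancer" &
                       d$date >= idx - 3650 & d$date <= idx))
  }
  # no two index events for one patient fall within 365 days
  gaps <- unlist(tapply(as.numeric(ev$index_date), ev$patient_id,
                        function(x) diff(sort(x))))
  if (length(gaps) > 0) expect_true(all(gaps > 365))
})

test_that("synthetic annual incident rates stay in the published 14-23% band", {
  ds <- generate_dataset(sim_config(n_patients = 4000, seed = 5))
  res <- run_phenotyping(ds, with_profiles = FALSE)
  inc <- res$annual_series[res$annual_series$series == "incident", ]
  expect_true(all(inc$rate >= 14 & inc$rate <= 23))
})
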