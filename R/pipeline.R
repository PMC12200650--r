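#' Run the full phenotyping pipeline on a dataset
#'
#' Chains drug preparation, cohort construction, long-term-therapy
#' classification, discontinuation detection, covariate profiling and the
#' assembly of the three annual rate series. The nesting invariant
#' (discontinuers within L-TOT users within incident users, per year) is
#' asserted at run time.
#'
#' @param dataset A `synthetic_cprd` list or any list with `patients`,
#'   `prescriptions` and `diagnoses` tables in the documented schemas.
#' @param study_start,study_end Study window; default from the dataset's
#'   config when present.
#' @param data_horizon Last date usable for discontinuation confirmation;
#'   defaults to 550 days past the study end (capped at the config's
#'   `data_end` when known), so late-study discontinuations remain
#'   confirmable.
#' @param plaus A [plausibility_config()].
#' @param with_profiles Build covariate profiles and the baseline table
#'   for L-TOT events (default TRUE).
#' @return A list with `clean_rx`, `events`, `classifications`,
#'   `discontinuations`, `annual_series`, `registered_by_year`, and (when
#'   requested) `profiles` and `table1`.
#' @export
run_phenotyping <- function(dataset,
                            study_start = NULL, study_end = NULL,
                            data_horizon = NULL,
                            plaus = plausibility_config(),
                            with_profiles = TRUE) {
  cfg <- dataset$config
  if (is.null(study_start)) study_start <- cfg$study_start
  if (is.null(study_end)) study_end <- cfg$study_end
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.null(data_horizon)) {
    data_horizon <- study_end + 550
    if (!is.null(cfg$data_end)) data_horizon <- min(data_horizon,
                                                    cfg$data_end)
  }
  products <- if (!is.null(cfg$formulary)) cfg$formulary
              else default_formulary()

  clean_rx <- prepare_prescriptions(dataset$prescriptions, products, plaus)
  events <- build_cohort(clean_rx, dataset$patients, dataset$diagnoses,
                         study_start, study_end)
  classifications <- detect_ltot(events, clean_rx)
  discontinuations <- detect_discontinuation(classifications, clean_rx,
                                             dataset$patients, data_horizon)
  years <- year_of(study_start):year_of(study_end)
  reg <- registered_patients_by_year(dataset$patients, years)
  annual_series <- assemble_annual_series(events, classifications,
                                          discontinuations, reg)
  out <- list(clean_rx = clean_rx, events = events,
              classifications = classifications,
              discontinuations = discontinuations,
              annual_series = annual_series,
              registered_by_year = reg)
  if (with_profiles && any(classifications$is_ltot)) {
    ltot_events <- classifications[classifications$is_ltot, ]
    profiles <- assemble_profiles(ltot_events, clean_rx,
                                  dataset$diagnoses, dataset$patients)
    disc_key <- paste(discontinuations$patient_id,
                      discontinuations$index_date)[discontinuations$confirmed]
    group <- ifelse(paste(profiles$patient_id, profiles$index_date) %in%
                      disc_key, "discontinuer", "ltot_nondiscontinuer")
    out$profiles <- profiles
    out$table1 <- build_table1(profiles, group)
  }
  out
}

#' Fit the segmented trend models for all three annual series
#'
#' Fits the main segmented negative-binomial model per series, plus the
#' two sensitivity fits (breakpoint year included; Poisson family), and
#' the structural-break scan on the incident series.
#'
#' @param annual_series Stacked series data.frame from
#'   [assemble_annual_series()] or built via [counts_to_series()].
#' @param spec A [segmented_model_spec()].
#' @return A list with `fits`, `sensitivity` (both named by series),
#'   `break_scan`, and `table3`, a tidy per-series coefficient table.
#' @export
run_trends <- function(annual_series, spec = segmented_model_spec()) {
  kinds <- unique(annual_series$series)
  fits <- lapply(kinds, function(k) {
    fit_segmented(annual_series[annual_series$series == k, ], spec)
  })
  names(fits) <- kinds
  sens <- lapply(kinds, function(k) {
    run_sensitivity(annual_series[annual_series$series == k, ], spec)
  })
  names(sens) <- kinds
  scan <- tryCatch(
    structural_break_scan(annual_series[annual_series$series == kinds[1], ]),
    error = function(e) NULL)
  tab3 <- do.call(rbind, lapply(kinds, function(k) {
    cf <- fits[[k]]$coefficients
    cf <- cf[cf$term != "beta0", ]
    cf$series <- k
    cf$family <- fits[[k]]$family
    cf[, c("series", "term", "label", "irr", "ci_low", "ci_high",
           "p_value", "significant", "family")]
  }))
  rownames(tab3) <- NULL
  list(fits = fits, sensitivity = sens, break_scan = scan, table3 = tab3)
}
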