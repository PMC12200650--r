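#' Plausibility bounds for prescription cleaning
#'
#' Values outside these bounds are treated as missing and imputed. The
#' defaults reflect routine UK primary-care dispensing: quantities of
#' 1-1000 dose units per issue, at most 24 units per day, durations of
#' 1-90 days, and a 90-day cap on any single issue's derived supply.
#'
#' @param quantity_range Closed range of plausible dispensed unit counts.
#' @param daily_dose_range Plausible units/day: the lower bound is
#'   exclusive (a zero daily dose is meaningless), the upper inclusive.
#' @param duration_range Closed range of plausible recorded durations.
#' @param max_supply_days Cap applied to derived supply days.
#' @return A list of class `plausibility_config`.
#' @export
plausibility_config <- function(quantity_range = c(1, 1000),
                                daily_dose_range = c(0, 24),
                                duration_range = c(1, 90),
                                max_supply_days = 90) {
  structure(list(quantity_range = quantity_range,
                 daily_dose_range = daily_dose_range,
                 duration_range = duration_range,
                 max_supply_days = max_supply_days),
            class = "plausibility_config")
}

plausible_quantity <- function(x, plaus) {
  !is.na(x) & is.finite(x) &
    x >= plaus$quantity_range[1] & x <= plaus$quantity_range[2]
}

plausible_daily_dose <- function(x, plaus) {
  !is.na(x) & is.finite(x) &
    x > plaus$daily_dose_range[1] & x <= plaus$daily_dose_range[2]
}

plausible_duration <- function(x, plaus) {
  !is.na(x) & is.finite(x) &
    x >= plaus$duration_range[1] & x <= plaus$duration_range[2]
}

#' Impute missing or implausible prescription fields
#'
#' Population-level imputation: a missing or implausible `quantity` or
#' `daily_dose_units` is replaced by the median of the plausible observed
#' values for the same product; if a product has no plausible observations
#' anywhere, the formulary's typical values are used; records that still
#' cannot be completed are dropped, with per-reason counts attached as the
#' `"dropped"` attribute. Implausible recorded durations are blanked (a
#' missing duration is ordinary — most issues carry none — so blanking is
#' not flagged). Imputed fields are flagged in `imputed_quantity` /
#' `imputed_daily_dose`; input row order is preserved.
#'
#' Running the operation twice gives the same result as running it once:
#' imputed values are medians of plausible values, hence plausible.
#'
#' @param records Prescription data.frame with columns `patient_id`,
#'   `issue_date`, `product_id`, `quantity`, `daily_dose_units`,
#'   `duration_days`.
#' @param products Product table (see [default_formulary()]).
#' @param plaus A [plausibility_config()].
#' @return The records with all quantities and daily doses present and
#'   plausible, plus the two imputation flag columns.
#' @export
impute_missing_fields <- function(records, products,
                                  plaus = plausibility_config()) {
  if (nrow(records) == 0) {
    records$imputed_quantity <- logical(0)
    records$imputed_daily_dose <- logical(0)
    attr(records, "dropped") <- c(no_quantity = 0L, no_daily_dose = 0L)
    return(records)
  }
  q_ok <- plausible_quantity(records$quantity, plaus)
  d_ok <- plausible_daily_dose(records$daily_dose_units, plaus)

  med_by_product <- function(values, ok) {
    v <- values
    v[!ok] <- NA_real_
    meds <- tapply(v, records$product_id, stats::median, na.rm = TRUE)
    unname(meds[as.character(records$product_id)])
  }
  q_med <- med_by_product(records$quantity, q_ok)
  d_med <- med_by_product(records$daily_dose_units, d_ok)

  # formulary fallbacks for products with no plausible record anywhere
  pidx <- match(records$product_id, products$product_id)
  d_fallback <- products$typical_daily_units[pidx]
  q_fallback <- d_fallback * products$typical_supply_days[pidx]

  q_new <- ifelse(q_ok, records$quantity,
                  ifelse(!is.na(q_med), q_med, q_fallback))
  d_new <- ifelse(d_ok, records$daily_dose_units,
                  ifelse(!is.na(d_med), d_med, d_fallback))

  keep <- !is.na(q_new) & !is.na(d_new)
  dropped <- c(no_quantity = sum(is.na(q_new)),
               no_daily_dose = sum(is.na(d_new) & !is.na(q_new)))

  prev_q <- if ("imputed_quantity" %in% names(records))
    records$imputed_quantity else FALSE
  prev_d <- if ("imputed_daily_dose" %in% names(records))
    records$imputed_daily_dose else FALSE
  records$quantity <- q_new
  records$daily_dose_units <- d_new
  records$imputed_quantity <- !q_ok | prev_q
  records$imputed_daily_dose <- !d_ok | prev_d
  dur_ok <- plausible_duration(records$duration_days, plaus)
  records$duration_days[!dur_ok] <- NA_integer_

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Derive supply days for a prescription issue
#'
#' A recorded plausible duration takes precedence; otherwise supply days
#' are `ceiling(quantity / daily_dose_units)`. The result is clamped to
#' `[1, max_supply_days]`.
#'
#' @param quantity Dispensed unit count (imputed, plausible).
#' @param daily_dose_units Units per day (imputed, plausible, > 0).
#' @param duration_days Recorded duration or `NA`.
#' @param max_supply_days Upper clamp, default 90.
#' @return Integer vector of supply days, each in `[1, max_supply_days]`.
#' @export
#' @examples
#' derive_supply_days(56, 2, NA)    # 28
#' derive_supply_days(56, 2, 30)    # recorded duration wins: 30
#' derive_supply_days(1000, 1, NA)  # clamped: 90
derive_supply_days <- function(quantity, daily_dose_units,
                               duration_days = NA_integer_,
                               max_supply_days = 90) {
  if (any(is.na(daily_dose_units) | daily_dose_units <= 0)) {
    stop("daily_dose_units must be positive after imputation")
  }
  derived <- ceiling(quantity / daily_dose_units)
  out <- ifelse(!is.na(duration_days), duration_days, derived)
  as.integer(pmin(pmax(out, 1), max_supply_days))
}

#' Daily dose in oral morphine milligram equivalents
#'
#' `daily_dose_units * strength_mg * mme_factor`. Products flagged as
#' excluded (opioid-dependence treatments) must be filtered beforehand.
#'
#' @param daily_dose_units Units per day.
#' @param strength_mg Active opioid mg per unit.
#' @param mme_factor Oral morphine equivalence multiplier per mg.
#' @param excluded_flag Logical; any `TRUE` is an error.
#' @return Numeric mg/day.
#' @export
#' @examples
#' compute_daily_mme(4, 50, 0.1)  # tramadol 50mg x4/day -> 20 MME
compute_daily_mme <- function(daily_dose_units, strength_mg, mme_factor,
                              excluded_flag = FALSE) {
  if (any(excluded_flag)) {
    stop("excluded products must be removed before MME conversion")
  }
  daily_dose_units * strength_mg * mme_factor
}

#' Clean raw prescription issues into analysable exposures
#'
#' The full drug-preparation pass: validates product coverage, removes
#' products flagged as excluded (methadone, sublingual buprenorphine),
#' imputes missing/implausible quantities and daily doses, derives supply
#' days, converts to daily oral morphine milligram equivalents, and
#' attaches potency/action classes. Supply intervals are closed:
#' `supply_end = supply_start + supply_days - 1`.
#'
#' @param records Raw prescription data.frame (see
#'   [impute_missing_fields()] for required columns).
#' @param products Product table covering every `product_id` in `records`.
#' @param plaus A [plausibility_config()].
#' @return A data.frame of clean prescriptions: `patient_id`,
#'   `product_id`, `supply_start`, `supply_days`, `supply_end`,
#'   `daily_mme`, `potency_class`, `action_class`, `imputed_quantity`,
#'   `imputed_daily_dose`. Removal counts are attached as the
#'   `"preparation_log"` attribute.
#' @export
prepare_prescriptions <- function(records, products,
                                  plaus = plausibility_config()) {
  unknown <- setdiff(unique(records$product_id), products$product_id)
  if (length(unknown) > 0) {
    stop("unknown product_id(s): ", paste(unknown, collapse = ", "))
  }
  n_input <- nrow(records)
  pidx <- match(records$product_id, products$product_id)
  excl <- products$excluded_flag[pidx]
  records <- records[!excl, , drop = FALSE]
  n_excluded <- sum(excl)

  records <- impute_missing_fields(records, products, plaus)
  dropped <- attr(records, "dropped")

  if (nrow(records) == 0) {
    out <- data.frame(patient_id = character(0),
                      product_id = character(0),
                      supply_start = as.Date(character(0)),
                      supply_days = integer(0),
                      supply_end = as.Date(character(0)),
                      daily_mme = numeric(0),
                      potency_class = character(0),
                      action_class = character(0),
                      imputed_quantity = logical(0),
                      imputed_daily_dose = logical(0))
  } else {
    pidx <- match(records$product_id, products$product_id)
    supply_days <- derive_supply_days(records$quantity,
                                      records$daily_dose_units,
                                      records$duration_days,
                                      plaus$max_supply_days)
    out <- data.frame(
      patient_id = records$patient_id,
      product_id = records$product_id,
      supply_start = records$issue_date,
      supply_days = supply_days,
      supply_end = records$issue_date + supply_days - 1,
      daily_mme = compute_daily_mme(records$daily_dose_units,
                                    products$strength_mg[pidx],
                                    products$mme_factor[pidx]),
      potency_class = products$potency_class[pidx],
      action_class = products$action_class[pidx],
      imputed_quantity = records$imputed_quantity,
      imputed_daily_dose = records$imputed_daily_dose
    )
  }
  stopifnot(all(out$daily_mme > 0), all(out$supply_days >= 1))
  attr(out, "preparation_log") <- list(
    n_input = n_input,
    n_excluded_product = n_excluded,
    n_dropped_unimputable = sum(dropped))
  out
}
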