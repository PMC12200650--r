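#' Default synthetic opioid formulary
#'
#' A small product metadata table in the shape expected by the drug
#' preparation step: one row per prescribable opioid product with its unit
#' strength, oral morphine-equivalence factor per mg, potency class
#' (weak/strong), action class (short/long acting), and an exclusion flag
#' for products whose primary indication is opioid-dependence treatment
#' rather than analgesia (methadone and sublingual buprenorphine).
#'
#' Strengths and conversion factors follow the standardized factors in
#' common pharmacoepidemiological use (codeine, tramadol and
#' dihydrocodeine 0.1; morphine 1.0; oxycodone 1.5). The transdermal
#' buprenorphine row is parameterised per patch-day: `strength_mg` is the
#' mg of buprenorphine delivered per day and `typical_daily_units` is 1,
#' so its daily morphine-equivalent dose is `strength_mg * mme_factor`.
#'
#' `typical_daily_units` and `typical_supply_days` are formulary-level
#' fallbacks used by imputation when a product has no observed plausible
#' values at all, and by the synthetic generator as prescribing defaults.
#'
#' @return A data.frame with columns `product_id`, `product_name`,
#'   `strength_mg`, `mme_factor`, `potency_class`, `action_class`,
#'   `excluded_flag`, `typical_daily_units`, `typical_supply_days`.
#' @export
#' @examples
#' default_formulary()
default_formulary <- function() {
  data.frame(
    product_id = c("OPI-COD30", "OPI-TRA50", "OPI-DHC30", "OPI-MOR10",
                   "OPI-OXY5", "OPI-BUP-TD", "OPI-MET5", "OPI-BUP-SL"),
    product_name = c("codeine 30mg tablet", "tramadol 50mg capsule",
                     "dihydrocodeine 30mg tablet",
                     "morphine sulfate 10mg IR tablet",
                     "oxycodone 5mg IR capsule",
                     "buprenorphine transdermal patch (0.24mg/day)",
                     "methadone 5mg tablet",
                     "buprenorphine 2mg sublingual tablet"),
    strength_mg = c(30, 50, 30, 10, 5, 0.24, 5, 2),
    mme_factor = c(0.1, 0.1, 0.1, 1.0, 1.5, 75, 4.7, 30),
    potency_class = c("weak", "weak", "weak", "strong", "strong",
                      "strong", "strong", "strong"),
    action_class = c("short-acting", "short-acting", "short-acting",
                     "short-acting", "short-acting", "long-acting",
                     "long-acting", "short-acting"),
    excluded_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE, TRUE),
    typical_daily_units = c(8, 4, 6, 2, 2, 1, 1, 1),
    typical_supply_days = c(28, 28, 28, 28, 28, 28, 28, 28),
    stringsAsFactors = FALSE
  )
}

#' Read or write a product metadata table
#'
#' CSV round-trip for the product table used by [prepare_prescriptions()].
#'
#' @param path File path.
#' @param products A product table as returned by [default_formulary()].
#' @return `read_product_table` returns the product data.frame.
#' @export
read_product_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("product_id", "strength_mg", "mme_factor", "potency_class",
                "action_class", "excluded_flag")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    stop("product table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out$excluded_flag <- as.logical(out$excluded_flag)
  out
}

#' @rdname read_product_table
#' @export
write_product_table <- function(products, path) {
  utils::write.csv(products, path, row.names = FALSE)
  invisible(path)
}

#' Published annual opioid-utilisation counts, UK primary care 2009-2019
#'
#' The packaged reference series of annual counts from a UK CPRD Aurum
#' opioid-utilisation study: per calendar year, the number of registered
#' patients, incident opioid users among them, L-TOT users among the
#' incident users, and L-TOT discontinuers among the L-TOT users. These
#' counts are the denominator/numerator pairs behind the three annual rate
#' series and the segmented trend models; shipping them lets the
#' statistical layer be exercised independently of any raw-record
#' pipeline.
#'
#' @return A data.frame with columns `year`, `registered_patients`,
#'   `incident_users`, `ltot_users`, `ltot_discontinuers`.
#' @seealso [counts_to_series()] to reshape into per-outcome rate series.
#' @export
#' @examples
#' head(annual_counts_fixture())
annual_counts_fixture <- function() {
  path <- system.file("extdata", "uk_annual_opioid_counts_2009_2019.csv",
                      package = "opioidtrends", mustWork = TRUE)
  utils::read.csv(path)
}

#' Reshape an annual count table into a rate series
#'
#' Builds the numerator/denominator series for one of the three outcomes:
#' incident users over registered patients, L-TOT users over incident
#' users, or L-TOT discontinuers over L-TOT users.
#'
#' @param counts A data.frame shaped like [annual_counts_fixture()].
#' @param kind One of `"incident"`, `"ltot"`, `"discontinuer"`.
#' @return A data.frame with columns `series`, `year`, `numerator`,
#'   `denominator` and `rate` (percent).
#' @export
counts_to_series <- function(counts,
                             kind = c("incident", "ltot", "discontinuer")) {
  kind <- match.arg(kind)
  cols <- switch(kind,
    incident     = c("incident_users", "registered_patients"),
    ltot         = c("ltot_users", "incident_users"),
    discontinuer = c("ltot_discontinuers", "ltot_users"))
  out <- data.frame(series = kind,
                    year = counts$year,
                    numerator = counts[[cols[1]]],
                    denominator = counts[[cols[2]]])
  compute_yearly_rates(out)
}
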