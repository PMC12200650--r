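#' Configuration for the synthetic primary-care data generator
#'
#' Describes the study conditions the generator emulates: the registered
#' population size, study window, per-year incident-episode hazards among
#' at-risk patients, the probability that an incident episode follows a
#' long-term-therapy prescription pattern, the probability that such an
#' episode discontinues in its second year, post-break multipliers for
#' intervention experiments, the product formulary, and field-level
#' missingness rates.
#'
#' The defaults emulate the magnitude and shape of a UK primary-care
#' opioid cohort scaled down roughly 100-fold: about 13 thousand
#' registered patients per year, annual incident rates drifting from ~21%
#' down to ~16% of registered patients across 2009-2019, an 11.4%
#' episode-level probability of long-term therapy and a 4.8%
#' discontinuation probability. The per-year hazards are set above the
#' target registered-denominator rates because patients in post-episode
#' washout are not at risk; see the package vignette for the calibration
#' arithmetic. Because no generative description of the real population
#' exists, all distributional choices here are stand-ins with the right
#' statistical structure, not estimates.
#'
#' @param n_patients Number of patients to simulate.
#' @param study_start,study_end Study window (coerced to Date).
#' @param data_end Last date covered by the data extract; must be on or
#'   after `study_end`. The default extends 550 days past the study end so
#'   that discontinuations indexed late in the study remain confirmable.
#' @param annual_incidence Named numeric vector, year to per-year hazard
#'   of starting an incident episode for an at-risk patient.
#' @param p_ltot Probability an incident episode is a long-term-therapy
#'   episode.
#' @param p_discontinue Probability a long-term episode discontinues in
#'   its second year.
#' @param break_year Calendar year after which the post-break multipliers
#'   apply.
#' @param step_multiplier,slope_multiplier Positive multipliers applied to
#'   the hazards of years after `break_year`: hazard is multiplied by
#'   `step_multiplier * slope_multiplier^(year - break_year - 1)`. Both
#'   default to 1 (the default hazard schedule already encodes the
#'   realistic trend).
#' @param formulary Product table, default [default_formulary()].
#' @param product_weights Named sampling weights over non-excluded
#'   formulary products for episode product choice.
#' @param missingness Named list of masking rates: `quantity`,
#'   `daily_dose_units` (set to `NA`), `implausible_quantity` (set to a
#'   negative value), `imd_quintile`, `ethnicity`, `smoking`, `drinking`.
#' @param p_cncp,p_cancer,p_nmsc Per-patient probabilities of carrying a
#'   chronic non-cancer pain, cancer, or non-melanoma skin cancer code.
#' @param p_transfer,p_death Probabilities of leaving the practice or
#'   dying before the data end.
#' @param seed Integer RNG seed; identical config and seed give
#'   byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 14000,
                       study_start = "2009-01-01",
                       study_end = "2019-12-31",
                       data_end = NULL,
                       annual_incidence = NULL,
                       p_ltot = 0.114,
                       p_discontinue = 0.048,
                       break_year = 2014L,
                       step_multiplier = 1,
                       slope_multiplier = 1,
                       formulary = default_formulary(),
                       product_weights = c("OPI-COD30" = 0.40,
                                           "OPI-TRA50" = 0.25,
                                           "OPI-DHC30" = 0.16,
                                           "OPI-MOR10" = 0.08,
                                           "OPI-OXY5" = 0.06,
                                           "OPI-BUP-TD" = 0.05),
                       missingness = list(quantity = 0.02,
                                          daily_dose_units = 0.02,
                                          implausible_quantity = 0.005,
                                          imd_quintile = 0.02,
                                          ethnicity = 0.10,
                                          smoking = 0.005,
                                          drinking = 0.29),
                       p_cncp = 0.85, p_cancer = 0.03, p_nmsc = 0.02,
                       p_transfer = 0.05, p_death = 0.03,
                       seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.null(data_end)) data_end <- study_end + 550 else
    data_end <- as.Date(data_end)
  if (is.null(annual_incidence)) {
    yrs <- year_of(study_start):year_of(study_end)
    # hazard drifts down post-2014 like the published rate series
    haz <- stats::approx(x = c(2009, 2013, 2015, 2019),
                         y = c(0.30, 0.30, 0.29, 0.24),
                         xout = pmin(pmax(yrs, 2009), 2019))$y
    annual_incidence <- stats::setNames(haz, yrs)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    study_start = study_start, study_end = study_end, data_end = data_end,
    annual_incidence = annual_incidence,
    p_ltot = p_ltot, p_discontinue = p_discontinue,
    break_year = as.integer(break_year),
    step_multiplier = step_multiplier,
    slope_multiplier = slope_multiplier,
    formulary = formulary, product_weights = product_weights,
    missingness = missingness,
    p_cncp = p_cncp, p_cancer = p_cancer, p_nmsc = p_nmsc,
    p_transfer = p_transfer, p_death = p_death,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$annual_incidence, cfg$p_ltot, cfg$p_discontinue,
             unlist(cfg$missingness), cfg$p_cncp, cfg$p_cancer, cfg$p_nmsc,
             cfg$p_transfer, cfg$p_death)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_patients < 0) stop("n_patients must be non-negative")
  if (!(cfg$study_start < as.Date(sprintf("%d-01-01", cfg$break_year)) &&
        cfg$break_year < year_of(cfg$study_end))) {
    stop("require study_start < break_year < study_end")
  }
  if (cfg$study_end > cfg$data_end) stop("data_end must be >= study_end")
  if (nrow(cfg$formulary) == 0) stop("formulary must be non-empty")
  if (cfg$step_multiplier <= 0 || cfg$slope_multiplier <= 0) {
    stop("multipliers must be positive")
  }
  if (!all(names(cfg$product_weights) %in% cfg$formulary$product_id)) {
    stop("product_weights reference unknown products")
  }
  invisible(cfg)
}

empty_dataset <- function(cfg) {
  list(
    patients = data.frame(patient_id = character(0), sex = character(0),
                          birth_year = integer(0),
                          registration_start = as.Date(character(0)),
                          registration_end = as.Date(character(0)),
                          death_date = as.Date(character(0)),
                          last_collection_date = as.Date(character(0)),
                          region = character(0), imd_quintile = integer(0),
                          ethnicity = character(0), smoking = character(0),
                          drinking = character(0)),
    prescriptions = data.frame(patient_id = character(0),
                               issue_date = as.Date(character(0)),
                               product_id = character(0),
                               quantity = numeric(0),
                               daily_dose_units = numeric(0),
                               duration_days = integer(0)),
    diagnoses = data.frame(patient_id = character(0),
                           date = as.Date(character(0)),
                           category = character(0)),
    episodes = data.frame(patient_id = character(0),
                          index_date = as.Date(character(0)),
                          product_id = character(0),
                          planted_ltot = logical(0),
                          planted_discontinuer = logical(0)),
    config = cfg)
}

# prescription pattern templates (day offsets from the episode index).
# Patterns are deliberately unambiguous with respect to the L-TOT and
# discontinuation rules so planted labels double as ground truth:
#  - long-term, persistent: 28-day supplies issued every 28 days through
#    day 812 (well past the second follow-up year);
#  - long-term, discontinuing: the same refills through day 336, then one
#    short 7-day issue at day 364, so the opioid-free gap starts on day
#    371 (inside the second year) and confirms by day 550;
#  - short-term: one issue at the index and, usually, a second isolated
#    issue a few months later.
episode_scripts <- function(episodes, cfg) {
  f <- cfg$formulary
  mk <- function(ep, offs, supply) {
    if (nrow(ep) == 0 || length(offs) == 0) return(NULL)
    k <- length(offs)
    data.frame(patient_id = rep(ep$patient_id, each = k),
               issue_date = rep(ep$index_date, each = k) + offs,
               product_id = rep(ep$product_id, each = k),
               supply = rep(supply, nrow(ep)))
  }
  persist <- episodes[episodes$planted_ltot & !episodes$planted_discontinuer, ]
  disc <- episodes[episodes$planted_discontinuer, ]
  short <- episodes[!episodes$planted_ltot, ]

  parts <- list(
    mk(persist, seq(0L, 812L, by = 28L), 28L),
    mk(disc, seq(0L, 336L, by = 28L), 28L),
    mk(disc, 364L, 7L)
  )
  if (nrow(short) > 0) {
    s1 <- sample(7:28, nrow(short), replace = TRUE)
    parts[[length(parts) + 1]] <- data.frame(
      patient_id = short$patient_id,
      issue_date = short$index_date,
      product_id = short$product_id,
      supply = s1)
    has2 <- stats::runif(nrow(short)) < 0.6
    if (any(has2)) {
      parts[[length(parts) + 1]] <- data.frame(
        patient_id = short$patient_id[has2],
        issue_date = short$index_date[has2] +
          sample(120:300, sum(has2), replace = TRUE),
        product_id = short$product_id[has2],
        supply = sample(7:28, sum(has2), replace = TRUE))
    }
  }
  rx <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  fidx <- match(rx$product_id, f$product_id)
  units <- f$typical_daily_units[fidx]
  data.frame(patient_id = rx$patient_id,
             issue_date = rx$issue_date,
             product_id = rx$product_id,
             quantity = units * rx$supply,
             daily_dose_units = units,
             duration_days = ifelse(stats::runif(nrow(rx)) < 0.3,
                                    as.integer(rx$supply), NA_integer_))
}

#' Generate a synthetic CPRD-Aurum-like dataset
#'
#' Simulates a patient register, an opioid prescription-issue table, and a
#' coded-event table (diagnoses plus concurrent-drug-class exposures) with
#' the statistical structure the downstream analysis assumes. Incident
#' opioid episodes are planted as explicit templates — an index issue plus
#' a refill pattern chosen by Bernoulli draws of the long-term-therapy and
#' discontinuation labels — and the planted labels are returned alongside
#' the data (`$episodes`) as ground truth for phenotyper validation.
#' Episodes are only planted where the patient remains observable long
#' enough for the label to be verifiable, and the label draws are
#' unconditional, so planted-label fractions stay binomial at the
#' configured probabilities. Missing and implausible field values are
#' injected after generation at the configured rates. Output is
#' deterministic given the config (including its seed).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_cprd` with data.frames `patients`,
#'   `prescriptions`, `diagnoses`, `episodes` (ground truth) and the
#'   `config`.
#' @export
generate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  if (n == 0) return(empty_dataset(cfg))

  study_years <- year_of(cfg$study_start):year_of(cfg$study_end)

  ## -- patient register ----------------------------------------------
  pid <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  birth_year <- sample(1925:1990, n, replace = TRUE)
  early <- stats::runif(n) < 0.8
  span <- as.integer(cfg$study_end - cfg$study_start) - 400L
  reg_start <- cfg$study_start +
    ifelse(early, -sample(365:4000, n, replace = TRUE),
           sample(0:span, n, replace = TRUE))
  reg_end <- rep(cfg$data_end, n)
  transfer <- stats::runif(n) < cfg$p_transfer
  reg_end[transfer] <- pmin(reg_start[transfer] +
                              sample(400:4000, sum(transfer), replace = TRUE),
                            cfg$data_end)
  death_date <- rep(as.Date(NA), n)
  dies <- stats::runif(n) < cfg$p_death
  death_date[dies] <- pmin(reg_start[dies] +
                             sample(500:4200, sum(dies), replace = TRUE),
                           cfg$data_end)
  reg_end <- pmin(reg_end, death_date, na.rm = TRUE)
  patients <- data.frame(
    patient_id = pid, sex = sex, birth_year = birth_year,
    registration_start = reg_start, registration_end = reg_end,
    death_date = death_date,
    last_collection_date = cfg$data_end,
    region = sample(c("North England", "Midland", "South England",
                      "London"), n, replace = TRUE,
                    prob = c(0.31, 0.20, 0.36, 0.13)),
    imd_quintile = sample(1:5, n, replace = TRUE,
                          prob = c(0.17, 0.19, 0.18, 0.20, 0.26)),
    ethnicity = sample(c("White", "Asian", "Black", "Mixed", "Other"),
                       n, replace = TRUE,
                       prob = c(0.87, 0.06, 0.04, 0.01, 0.02)),
    smoking = sample(c("Current", "Never", "Former"), n, replace = TRUE,
                     prob = c(0.22, 0.46, 0.32)),
    drinking = sample(c("Current", "Never", "Former"), n, replace = TRUE,
                      prob = c(0.76, 0.22, 0.02)))

  ## -- coded events ---------------------------------------------------
  rand_dates <- function(from, to) {
    from + floor(stats::runif(length(from)) *
                   (as.numeric(to - from) + 1))
  }
  dx_parts <- list()
  add_dx <- function(mask, category, dates) {
    if (any(mask)) {
      dx_parts[[length(dx_parts) + 1]] <<- data.frame(
        patient_id = pid[mask], date = dates[mask], category = category)
    }
  }
  has_cncp <- stats::runif(n) < cfg$p_cncp
  add_dx(has_cncp, "CNCP",
         pmin(reg_start + sample(0:300, n, replace = TRUE), cfg$data_end))
  add_dx(stats::runif(n) < cfg$p_cancer, "cancer",
         rand_dates(reg_start, reg_end))
  add_dx(stats::runif(n) < cfg$p_nmsc, "NMSC",
         rand_dates(reg_start, reg_end))
  event_rates <- c(anxiety = 0.15, depression = 0.20, RA = 0.02, OA = 0.08,
                   schizophrenia = 0.01, alcohol_dependence = 0.03,
                   epilepsy = 0.02, substance_misuse = 0.03,
                   diabetes = 0.08, copd = 0.06, mi = 0.03, chf = 0.02,
                   renal_disease = 0.02, liver_disease_mild = 0.01,
                   hemiplegia = 0.005, diabetes_complications = 0.02,
                   drug_benzodiazepines = 0.20, drug_antidepressants = 0.45,
                   drug_gabapentinoids = 0.01, drug_muscle_relaxants = 0.01,
                   drug_z_drugs = 0.12, drug_nsaids = 0.60)
  for (cat in names(event_rates)) {
    add_dx(stats::runif(n) < event_rates[[cat]], cat,
           rand_dates(reg_start, reg_end))
  }
  diagnoses <- do.call(rbind, dx_parts)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date), ]
  rownames(diagnoses) <- NULL

  ## -- planted incident episodes --------------------------------------
  # A two-year burn-in precedes the study window so the washout process
  # is in steady state by the first study year (without it, the first
  # year has no prescribing history and its incident rate overshoots).
  # Burn-in episodes fall outside the study window and never enter the
  # cohort; they only provide realistic prior exposure.
  obs_end <- pmin(reg_end, cfg$data_end)
  next_eligible <- pmax(reg_start + DAYS_YEAR, cfg$study_start - 730L)
  active_products <- names(cfg$product_weights)
  ep_parts <- list()
  plant_years <- (study_years[1] - 2L):study_years[length(study_years)]
  for (y in plant_years) {
    y_start <- as.Date(sprintf("%d-01-01", y))
    y_end <- as.Date(sprintf("%d-12-31", y))
    h <- if (as.character(y) %in% names(cfg$annual_incidence)) {
      cfg$annual_incidence[[as.character(y)]]
    } else {
      cfg$annual_incidence[[1]]  # burn-in years use the earliest hazard
    }
    if (y > cfg$break_year) {
      h <- h * cfg$step_multiplier *
        cfg$slope_multiplier^(y - cfg$break_year - 1)
    }
    h <- min(h, 1)
    cand <- which(next_eligible <= y_end)
    if (length(cand) == 0) next
    hit <- cand[stats::runif(length(cand)) < h]
    if (length(hit) == 0) next
    lo <- pmax(next_eligible[hit], y_start)
    idx <- lo + floor(stats::runif(length(hit)) *
                        (as.numeric(y_end - lo) + 1))
    # plant only where the episode outcome is fully observable
    ok <- obs_end[hit] >= pmin(idx + 910, cfg$data_end)
    hit <- hit[ok]; idx <- idx[ok]
    if (length(hit) == 0) next
    is_ltot <- stats::runif(length(hit)) < cfg$p_ltot
    is_disc <- is_ltot & stats::runif(length(hit)) < cfg$p_discontinue
    ep_parts[[length(ep_parts) + 1]] <- data.frame(
      patient_id = pid[hit], index_date = idx,
      product_id = sample(active_products, length(hit), replace = TRUE,
                          prob = cfg$product_weights),
      planted_ltot = is_ltot, planted_discontinuer = is_disc)
    last_issue_off <- ifelse(is_ltot & !is_disc, 812L,
                             ifelse(is_disc, 364L, 300L))
    next_eligible[hit] <- idx + last_issue_off + DAYS_YEAR + 1L +
      sample(0:60, length(hit), replace = TRUE)
  }
  if (length(ep_parts) == 0) {
    out <- empty_dataset(cfg)
    out$patients <- patients
    out$diagnoses <- diagnoses
    return(out)
  }
  episodes <- do.call(rbind, ep_parts)
  episodes <- episodes[order(episodes$patient_id, episodes$index_date), ]
  rownames(episodes) <- NULL

  ## -- prescriptions ---------------------------------------------------
  rx <- episode_scripts(episodes, cfg)
  # truncate at the end of each patient's observable record
  rx <- rx[rx$issue_date <= obs_end[match(rx$patient_id, pid)], ]

  # a sprinkle of opioid-dependence-treatment issues (excluded products)
  noise_pat <- which(stats::runif(n) < 0.01 & obs_end > reg_start + 100)
  if (length(noise_pat) > 0) {
    excl_ids <- cfg$formulary$product_id[cfg$formulary$excluded_flag]
    if (length(excl_ids) > 0) {
      nd <- rand_dates(reg_start[noise_pat] + 100, obs_end[noise_pat])
      rx <- rbind(rx, data.frame(
        patient_id = pid[noise_pat], issue_date = nd,
        product_id = sample(excl_ids, length(noise_pat), replace = TRUE),
        quantity = 28, daily_dose_units = 1, duration_days = NA_integer_))
    }
  }

  ## -- missingness / implausibility injection -------------------------
  m <- cfg$missingness
  nr <- nrow(rx)
  rx$quantity[stats::runif(nr) < m$quantity] <- NA_real_
  rx$daily_dose_units[stats::runif(nr) < m$daily_dose_units] <- NA_real_
  rx$quantity[stats::runif(nr) < m$implausible_quantity] <- -5
  patients$imd_quintile[stats::runif(n) < m$imd_quintile] <- NA_integer_
  patients$ethnicity[stats::runif(n) < m$ethnicity] <- NA_character_
  patients$smoking[stats::runif(n) < m$smoking] <- NA_character_
  patients$drinking[stats::runif(n) < m$drinking] <- NA_character_

  rx <- rx[order(rx$patient_id, rx$issue_date, rx$product_id), ]
  rownames(rx) <- NULL
  structure(list(patients = patients, prescriptions = rx,
                 diagnoses = diagnoses, episodes = episodes,
                 config = cfg), class = "synthetic_cprd")
}

#' Simulate an annual count series directly from the segmented model
#'
#' Draws annual numerators from the segmented count model itself (the
#' direct test harness for the trend-fitting layer): the mean for year `y`
#' is `exp(beta0 + beta1 t + beta2 I + beta3 X) * offset_y` with the
#' design coding of [build_design()], and counts are negative binomial
#' NB2 with the given dispersion (Poisson at dispersion zero, the NB
#' boundary). All years are generated, including any marked excluded —
#' exclusion is a fitting-time concern.
#'
#' @param beta Numeric length-4 vector (intercept, trend, step, slope
#'   change) on the log scale.
#' @param offsets Named numeric vector, year to positive denominator;
#'   at least 6 years.
#' @param dispersion NB2 alpha, >= 0; 0 draws Poisson counts.
#' @param break_year Breakpoint for the design coding, default 2014.
#' @param excluded_years Years marked as excluded (stored on the result;
#'   counts are still generated).
#' @param seed Integer seed.
#' @return Data.frame `year`, `numerator`, `denominator`, `rate` with the
#'   true means as attribute `"mu"` and `excluded_years` attached.
#' @export
generate_counts_from_model <- function(beta, offsets, dispersion = 0,
                                       break_year = 2014L,
                                       excluded_years = integer(0),
                                       seed = 1L) {
  if (length(offsets) == 0) stop("offsets must be non-empty")
  if (length(offsets) < 6) stop("offsets must cover at least 6 years")
  if (dispersion < 0) stop("dispersion must be non-negative")
  stopifnot(length(beta) == 4)
  years <- sort(as.integer(names(offsets)))
  offsets <- offsets[as.character(years)]
  des <- build_design(years, segmented_model_spec(
    break_year = break_year, excluded_years = integer(0)))
  mu <- exp(beta[1] + beta[2] * des$t + beta[3] * des$I + beta[4] * des$X +
              log(unname(offsets)))
  set.seed(seed)
  num <- if (dispersion == 0) stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  out <- data.frame(year = years, numerator = num,
                    denominator = unname(offsets))
  out$rate <- round(100 * out$numerator / out$denominator, 2)
  attr(out, "mu") <- mu
  attr(out, "excluded_years") <- as.integer(excluded_years)
  out
}

#' Write or read a synthetic dataset as CSV files
#'
#' Writes `patients.csv`, `prescriptions.csv`, `diagnoses.csv` and
#' `episodes.csv` (ISO-8601 dates) into a directory; `read_dataset`
#' restores them with the same column types so a written-then-read
#' dataset is identical to the original.
#'
#' @param dataset A `synthetic_cprd` list (the `config` is not written).
#' @param dir Directory path (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns
#'   a list with the four tables.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("patients", "prescriptions", "diagnoses", "episodes")) {
    utils::write.csv(dataset[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(name, dates, ints = character(0), logs = character(0),
                 nums = character(0)) {
    out <- utils::read.csv(file.path(dir, paste0(name, ".csv")),
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
    for (cl in dates) out[[cl]] <- as.Date(out[[cl]])
    for (cl in ints) out[[cl]] <- as.integer(out[[cl]])
    for (cl in logs) out[[cl]] <- as.logical(out[[cl]])
    for (cl in nums) out[[cl]] <- as.numeric(out[[cl]])
    out
  }
  list(
    patients = rd("patients",
                  c("registration_start", "registration_end", "death_date",
                    "last_collection_date"), ints = c("birth_year",
                                                      "imd_quintile")),
    prescriptions = rd("prescriptions", "issue_date",
                       ints = "duration_days",
                       nums = c("quantity", "daily_dose_units")),
    diagnoses = rd("diagnoses", "date"),
    episodes = rd("episodes", "index_date",
                  logs = c("planted_ltot", "planted_discontinuer")))
}
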