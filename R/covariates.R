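#' Standard Charlson condition weights
#'
#' Configurable condition-to-weight map used for the comorbidity score.
#' Keys must match the diagnosis categories of the event table; conditions
#' absent from the map contribute nothing. The classic weights are
#' shipped; pass a modified vector to re-weight or extend.
#'
#' @return Named integer vector of weights.
#' @export
charlson_weights <- function() {
  c(mi = 1L, chf = 1L, peripheral_vascular = 1L, cerebrovascular = 1L,
    dementia = 1L, copd = 1L, rheumatic = 1L, RA = 1L, peptic_ulcer = 1L,
    liver_disease_mild = 1L, diabetes = 1L,
    diabetes_complications = 2L, hemiplegia = 2L, renal_disease = 2L,
    liver_disease_severe = 3L, aids = 6L)
}

#' Grade a Charlson comorbidity score
#'
#' @param score Non-negative integer score(s).
#' @return `"low"` for 0-2, `"medium"` for 3-4, `"high"` for 5 and above.
#' @export
#' @examples
#' grade_cci(c(0, 2, 3, 4, 5, 9))
grade_cci <- function(score) {
  if (any(is.na(score)) || any(score < 0)) {
    stop("CCI score must be a non-negative integer")
  }
  ifelse(score <= 2, "low", ifelse(score <= 4, "medium", "high"))
}

#' Band a daily morphine-equivalent dose
#'
#' Left-closed, right-open bands: `[0,50)`, `[50,90)`, `[90,120)`,
#' `[120, Inf)`.
#'
#' @param mme_per_day Non-negative mg/day value(s).
#' @return Character band labels.
#' @export
#' @examples
#' categorize_dose(c(20.16, 50, 120))
categorize_dose <- function(mme_per_day) {
  if (any(is.na(mme_per_day)) || any(mme_per_day < 0)) {
    stop("daily MME must be non-negative")
  }
  as.character(cut(mme_per_day, breaks = c(0, 50, 90, 120, Inf),
                   labels = c("<50", "[50,90)", "[90,120)", ">=120"),
                   right = FALSE, include.lowest = TRUE))
}

COMORBIDITY_FLAGS <- c("RA", "OA", "anxiety", "depression", "schizophrenia",
                       "alcohol_dependence", "epilepsy", "substance_misuse")
DRUG_FLAGS <- c("drug_benzodiazepines", "drug_antidepressants",
                "drug_gabapentinoids", "drug_muscle_relaxants",
                "drug_z_drugs", "drug_nsaids")

AGE_BREAKS <- c(18, 30, 40, 50, 60, 70, 80, 90, Inf)
AGE_LABELS <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79",
                "80-89", ">=90")

unknown_if_missing <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  x
}

#' Assemble baseline covariate profiles for index events
#'
#' For each event: demographics at the index (age from year of birth, so
#' age = index year minus birth year), deprivation quintile, region,
#' ethnicity and lifestyle with missing values mapped to `"unknown"`;
#' comorbidity and concurrent-drug flags set when at least one qualifying
#' coded event falls in the five-year lookback `[index - 1825, index)`
#' (the index day itself excluded); the Charlson score summed over
#' distinct weighted conditions in the same lookback and graded; and the
#' first-year opioid dose summary (mean daily MME across issues with
#' supply starting in days 0-364, its dose band, and the weak-opioid /
#' short-acting flags, true only when every first-year product is weak,
#' respectively short-acting).
#'
#' @param events Index events.
#' @param clean_rx Clean prescriptions.
#' @param diagnoses Coded event table (`patient_id`, `date`, `category`);
#'   carries both diagnostic categories and concurrent-drug-class
#'   exposure events (categories prefixed `drug_`).
#' @param patients Patient table.
#' @param weights Charlson weight map, default [charlson_weights()].
#' @return One profile row per event.
#' @export
assemble_profiles <- function(events, clean_rx, diagnoses, patients,
                              weights = charlson_weights()) {
  pidx <- match(events$patient_id, patients$patient_id)
  age <- events$index_year - patients$birth_year[pidx]
  dx_by_pat <- split(diagnoses[, c("date", "category")],
                     diagnoses$patient_id)
  rx_by_pat <- split(seq_len(nrow(clean_rx)), clean_rx$patient_id)

  n <- nrow(events)
  flag_mat <- matrix(FALSE, n, length(c(COMORBIDITY_FLAGS, DRUG_FLAGS)),
                     dimnames = list(NULL, c(COMORBIDITY_FLAGS, DRUG_FLAGS)))
  cci <- integer(n)
  mean_mme <- numeric(n)
  all_weak <- logical(n)
  all_short <- logical(n)

  for (k in seq_len(n)) {
    idx <- events$index_date[k]
    dx <- dx_by_pat[[events$patient_id[k]]]
    if (!is.null(dx)) {
      in_lb <- dx$date >= idx - DAYS_5Y & dx$date < idx
      cats <- unique(dx$category[in_lb])
      flag_mat[k, ] <- colnames(flag_mat) %in% cats
      cci[k] <- sum(weights[intersect(cats, names(weights))])
    }
    rows <- rx_by_pat[[events$patient_id[k]]]
    d <- as.integer(clean_rx$supply_start[rows] - idx)
    fy <- rows[d >= 0 & d <= LTOT_WIN_HI]
    if (length(fy) > 0) {
      mean_mme[k] <- mean(clean_rx$daily_mme[fy])
      all_weak[k] <- all(clean_rx$potency_class[fy] == "weak")
      all_short[k] <- all(clean_rx$action_class[fy] == "short-acting")
    } else {
      mean_mme[k] <- NA_real_
    }
  }

  out <- data.frame(
    patient_id = events$patient_id,
    index_date = events$index_date,
    index_year = events$index_year,
    sex = unknown_if_missing(patients$sex[pidx]),
    age = age,
    age_band = as.character(cut(age, AGE_BREAKS, AGE_LABELS, right = FALSE)),
    imd_quintile = unknown_if_missing(patients$imd_quintile[pidx]),
    region = unknown_if_missing(patients$region[pidx]),
    ethnicity = unknown_if_missing(patients$ethnicity[pidx]),
    smoking = unknown_if_missing(patients$smoking[pidx]),
    drinking = unknown_if_missing(patients$drinking[pidx]),
    cci_score = cci,
    cci_grade = grade_cci(cci),
    mean_daily_mme = mean_mme,
    dose_band = ifelse(is.na(mean_mme), NA_character_,
                       categorize_dose(ifelse(is.na(mean_mme), 0, mean_mme))),
    weak_opioid = all_weak,
    short_acting = all_short
  )
  cbind(out, as.data.frame(flag_mat))
}

#' Baseline characteristics table by discontinuation group
#'
#' Counts and column percentages per level for every categorical variable
#' and flag, plus mean and SD for age and mean daily dose, by group
#' (L-TOT users who did not discontinue versus discontinuers).
#' Percentages are over the group totals; an empty group yields zero
#' counts without division errors.
#'
#' @param profiles Output of [assemble_profiles()].
#' @param group Character vector aligned with `profiles`, with values
#'   `"ltot_nondiscontinuer"` or `"discontinuer"`.
#' @return Long data.frame: `variable`, `level`, and per group `n_*`,
#'   `pct_*` columns (plus `mean_*`/`sd_*` rows for numeric variables).
#' @export
build_table1 <- function(profiles, group) {
  stopifnot(nrow(profiles) == length(group))
  groups <- c("ltot_nondiscontinuer", "discontinuer")
  stopifnot(all(group %in% groups))
  totals <- vapply(groups, function(g) sum(group == g), integer(1))

  cat_vars <- c("sex", "age_band", "imd_quintile", "region", "ethnicity",
                "smoking", "drinking", "cci_grade", "dose_band",
                COMORBIDITY_FLAGS, DRUG_FLAGS, "weak_opioid", "short_acting")
  rows <- list()
  for (v in cat_vars) {
    x <- profiles[[v]]
    if (is.logical(x)) {
      levels_v <- "TRUE"
      x <- as.character(x)
    } else {
      levels_v <- sort(unique(as.character(x)))
    }
    for (lev in levels_v) {
      ns <- vapply(groups, function(g) {
        sum(!is.na(x) & x == lev & group == g)
      }, integer(1))
      pct <- ifelse(totals > 0, 100 * ns / totals, 0)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lev,
        n_ltot = ns[1], pct_ltot = round(pct[1], 2),
        n_discontinuer = ns[2], pct_discontinuer = round(pct[2], 2))
    }
  }
  num_vars <- c("age", "mean_daily_mme")
  for (v in num_vars) {
    x <- profiles[[v]]
    ms <- vapply(groups, function(g) mean(x[group == g], na.rm = TRUE),
                 numeric(1))
    sds <- vapply(groups, function(g) stats::sd(x[group == g], na.rm = TRUE),
                  numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "mean_sd",
      n_ltot = totals[1], pct_ltot = round(ms[1], 2),
      n_discontinuer = totals[2], pct_discontinuer = round(ms[2], 2))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "sd",
      n_ltot = totals[1], pct_ltot = round(sds[1], 2),
      n_discontinuer = totals[2], pct_discontinuer = round(sds[2], 2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
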