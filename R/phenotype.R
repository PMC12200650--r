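# L-TOT evaluation window: days 30..364 after the index (index = day 0).
# The first 30 days are excluded from BOTH criteria; the window closes at
# the end of the first follow-up year.
LTOT_WIN_LO <- 30L
LTOT_WIN_HI <- 364L
LTOT_SPAN <- 90L       # criterion A: >=3 issues within a 90-consecutive-day span
LTOT_SUPPLY_MIN <- 90L # criterion B: >=90 distinct covered days in window
GAP_DAYS <- 180L       # discontinuation: >=180 consecutive opioid-free days
GAP_START_LO <- 365L   # the gap must start in the second follow-up year
GAP_START_HI <- 729L

# merge closed integer intervals [s_i, e_i] (pre-condition: some rows)
merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= me + 1L) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# Core L-TOT rule on day offsets from the index.
# issue_d: issue-day offsets; start_d/end_d: supply interval offsets.
classify_ltot_offsets <- function(issue_d, start_d, end_d) {
  iw <- sort(issue_d[issue_d >= LTOT_WIN_LO & issue_d <= LTOT_WIN_HI])
  n_issues <- length(iw)

  # criterion A: three issue dates inside the window within one 90-day span
  a_day <- NA_integer_
  if (n_issues >= 3) {
    span <- iw[-(1:2)] - iw[seq_len(n_issues - 2)]
    hit <- which(span <= LTOT_SPAN - 1L)
    if (length(hit) > 0) a_day <- iw[hit[1] + 2L]
  }

  # criterion B: >=90 distinct supply-covered days inside the window
  covered <- 0L
  b_day <- NA_integer_
  s <- pmax(start_d, LTOT_WIN_LO)
  e <- pmin(end_d, LTOT_WIN_HI)
  ok <- !is.na(s) & !is.na(e) & s <= e
  if (any(ok)) {
    m <- merge_intervals(s[ok], e[ok])
    lens <- m[, "end"] - m[, "start"] + 1L
    covered <- sum(lens)
    if (covered >= LTOT_SUPPLY_MIN) {
      cum <- cumsum(lens)
      j <- which(cum >= LTOT_SUPPLY_MIN)[1]
      before <- if (j == 1) 0L else cum[j - 1]
      b_day <- m[j, "start"] + (LTOT_SUPPLY_MIN - before) - 1L
    }
  }

  crit_a <- !is.na(a_day)
  crit_b <- !is.na(b_day)
  list(is_ltot = crit_a || crit_b,
       criterion = if (crit_a && crit_b) "both"
                   else if (crit_a) "count_window"
                   else if (crit_b) "supply_days"
                   else "none",
       qualification_day = if (crit_a || crit_b) min(a_day, b_day, na.rm = TRUE)
                           else NA_integer_,
       n_issues_in_window = n_issues,
       covered_days_in_window = as.integer(covered))
}

#' Classify index events as long-term opioid therapy
#'
#' Dual criterion over the evaluation window of days 30-364 after the
#' index: (A) three or more prescription issues inside the window falling
#' within some 90-consecutive-day span, or (B) at least 90 distinct
#' calendar days of the window covered by supply (overlapping supplies are
#' not double counted). The qualification date is the earliest day on
#' which either criterion is first satisfiable.
#'
#' @param events Index events (`patient_id`, `index_date`, ...).
#' @param clean_rx Clean prescriptions from [prepare_prescriptions()].
#' @return One row per event: `patient_id`, `index_date`, `is_ltot`,
#'   `criterion` (`none`/`count_window`/`supply_days`/`both`),
#'   `qualification_date`, `n_issues_in_window`,
#'   `covered_days_in_window`.
#' @export
detect_ltot <- function(events, clean_rx) {
  rx_by_pat <- split(seq_len(nrow(clean_rx)), clean_rx$patient_id)
  n <- nrow(events)
  is_ltot <- logical(n)
  criterion <- character(n)
  qual <- rep(as.Date(NA), n)
  n_iss <- integer(n)
  cov <- integer(n)
  for (k in seq_len(n)) {
    rows <- rx_by_pat[[events$patient_id[k]]]
    idx <- events$index_date[k]
    issue_d <- as.integer(clean_rx$supply_start[rows] - idx)
    start_d <- issue_d
    end_d <- as.integer(clean_rx$supply_end[rows] - idx)
    sel <- end_d >= LTOT_WIN_LO & start_d <= LTOT_WIN_HI
    res <- classify_ltot_offsets(
      issue_d[issue_d >= 0 & issue_d <= LTOT_WIN_HI],
      start_d[sel], end_d[sel])
    is_ltot[k] <- res$is_ltot
    criterion[k] <- res$criterion
    if (!is.na(res$qualification_day)) qual[k] <- idx + res$qualification_day
    n_iss[k] <- res$n_issues_in_window
    cov[k] <- res$covered_days_in_window
  }
  data.frame(patient_id = events$patient_id,
             index_date = events$index_date,
             index_year = events$index_year,
             is_ltot = is_ltot,
             criterion = criterion,
             qualification_date = qual,
             n_issues_in_window = n_iss,
             covered_days_in_window = cov)
}

#' Brute-force oracle for the L-TOT rule
#'
#' Exhaustive evaluation used as an independent check on
#' [detect_ltot()]: criterion A is tested by sliding every possible
#' 90-day span across the calendar and counting issue dates inside the
#' span intersected with the evaluation window; criterion B by marking
#' every covered day of the window on a day grid. Intended for small
#' instances.
#'
#' @param issue_d Integer day offsets of issues from the index.
#' @param start_d,end_d Integer day offsets of supply intervals.
#' @return List with `is_ltot`, `criterion`, `n_issues_in_window`,
#'   `covered_days_in_window`.
#' @export
brute_force_ltot <- function(issue_d, start_d, end_d) {
  stopifnot(length(issue_d) <= 200)
  iw <- issue_d[issue_d >= LTOT_WIN_LO & issue_d <= LTOT_WIN_HI]
  crit_a <- FALSE
  for (s in (LTOT_WIN_LO - LTOT_SPAN + 1L):LTOT_WIN_HI) {
    lo <- max(s, LTOT_WIN_LO)
    hi <- min(s + LTOT_SPAN - 1L, LTOT_WIN_HI)
    if (sum(iw >= lo & iw <= hi) >= 3) { crit_a <- TRUE; break }
  }
  days <- rep(FALSE, LTOT_WIN_HI - LTOT_WIN_LO + 1L)
  for (i in seq_along(start_d)) {
    lo <- max(start_d[i], LTOT_WIN_LO)
    hi <- min(end_d[i], LTOT_WIN_HI)
    if (lo <= hi) days[(lo - LTOT_WIN_LO + 1L):(hi - LTOT_WIN_LO + 1L)] <- TRUE
  }
  covered <- sum(days)
  crit_b <- covered >= LTOT_SUPPLY_MIN
  list(is_ltot = crit_a || crit_b,
       criterion = if (crit_a && crit_b) "both"
                   else if (crit_a) "count_window"
                   else if (crit_b) "supply_days"
                   else "none",
       n_issues_in_window = length(iw),
       covered_days_in_window = covered)
}

#' Detect discontinuation after long-term opioid therapy
#'
#' A discontinuation is an opioid-free gap of at least 180 days whose
#' first opioid-free day falls in the second follow-up year (days 365-729
#' after the index), with the whole 180-day confirmation window inside the
#' patient's observable data — the earlier of their registration end and
#' the data horizon. The horizon may extend beyond the study end so that
#' late-study events remain confirmable. The earliest qualifying gap is
#' reported.
#'
#' @param classifications Output of [detect_ltot()] (only rows with
#'   `is_ltot` are evaluated; others are returned unconfirmed).
#' @param clean_rx Clean prescriptions.
#' @param patients Patient table (`registration_end` bounds observability).
#' @param data_horizon Last date with usable prescription data.
#' @return One row per input event: `patient_id`, `index_date`,
#'   `confirmed`, `last_supply_end`, `gap_start`, `confirmation_date`.
#' @export
detect_discontinuation <- function(classifications, clean_rx, patients,
                                   data_horizon) {
  data_horizon <- as.Date(data_horizon)
  rx_by_pat <- split(seq_len(nrow(clean_rx)), clean_rx$patient_id)
  n <- nrow(classifications)
  confirmed <- logical(n)
  last_end <- rep(as.Date(NA), n)
  gap_start <- rep(as.Date(NA), n)
  conf_date <- rep(as.Date(NA), n)
  pidx <- match(classifications$patient_id, patients$patient_id)
  obs_end <- pmin(patients$registration_end[pidx], data_horizon)

  for (k in seq_len(n)) {
    if (!classifications$is_ltot[k]) next
    rows <- rx_by_pat[[classifications$patient_id[k]]]
    idx <- classifications$index_date[k]
    s <- as.integer(clean_rx$supply_start[rows] - idx)
    e <- as.integer(clean_rx$supply_end[rows] - idx)
    keep <- e >= 0L
    m <- merge_intervals(s[keep], e[keep])
    horizon_off <- as.integer(obs_end[k] - idx)
    # gaps: after each merged interval, up to the next one (or open-ended)
    gs <- m[, "end"] + 1L
    glen <- c(m[-1, "start"], NA) - gs  # NA: trailing, unbounded gap
    for (j in seq_along(gs)) {
      if (gs[j] < GAP_START_LO || gs[j] > GAP_START_HI) next
      if (!is.na(glen[j]) && glen[j] < GAP_DAYS) next
      if (gs[j] + GAP_DAYS - 1L > horizon_off) next
      confirmed[k] <- TRUE
      last_end[k] <- idx + gs[j] - 1L
      gap_start[k] <- idx + gs[j]
      conf_date[k] <- idx + gs[j] + GAP_DAYS - 1L
      break
    }
  }
  data.frame(patient_id = classifications$patient_id,
             index_date = classifications$index_date,
             index_year = classifications$index_year,
             confirmed = confirmed,
             last_supply_end = last_end,
             gap_start = gap_start,
             confirmation_date = conf_date)
}

#' Assemble the three annual numerator/denominator series
#'
#' Per calendar year of the index date: incident events over registered
#' patients, L-TOT classifications over incident events, and confirmed
#' discontinuations over L-TOT classifications. Discontinuations are
#' attributed to the index year of their L-TOT episode, keeping the
#' numerator nested in that year's denominator.
#'
#' @param events Index events.
#' @param classifications Output of [detect_ltot()].
#' @param discontinuations Output of [detect_discontinuation()].
#' @param registered_by_year Named vector from
#'   [registered_patients_by_year()].
#' @return A data.frame of all three series stacked (columns `series`,
#'   `year`, `numerator`, `denominator`, `rate`).
#' @export
assemble_annual_series <- function(events, classifications,
                                   discontinuations, registered_by_year) {
  years <- as.integer(names(registered_by_year))
  cnt <- function(yrs) {
    tab <- table(factor(yrs, levels = years))
    as.integer(tab)
  }
  n_inc <- cnt(events$index_year)
  n_ltot <- cnt(classifications$index_year[classifications$is_ltot])
  n_disc <- cnt(discontinuations$index_year[discontinuations$confirmed])
  if (any(n_ltot > n_inc) || any(n_disc > n_ltot) ||
      any(n_inc > unname(registered_by_year))) {
    stop("annual series are not nested (numerator exceeds denominator)")
  }
  rbind(
    compute_yearly_rates(data.frame(series = "incident", year = years,
                                    numerator = n_inc,
                                    denominator = unname(registered_by_year))),
    make_series_safe("ltot", years, n_ltot, n_inc),
    make_series_safe("discontinuer", years, n_disc, n_ltot)
  )
}

# rate series tolerant of zero denominators (empty cohorts in a year)
make_series_safe <- function(kind, years, num, den) {
  out <- data.frame(series = kind, year = years,
                    numerator = num, denominator = den)
  out$rate <- ifelse(den > 0, round(100 * num / den, 2), NA_real_)
  out
}
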