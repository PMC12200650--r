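#' Specification of a segmented annual count model
#'
#' Describes one interrupted-time-series fit: which year the time variable
#' is anchored at, the breakpoint year, which calendar years are dropped
#' from the likelihood (by default the breakpoint year itself, to avoid a
#' partial-exposure year contaminating either segment), the count family,
#' and the confidence level for Wald intervals.
#'
#' @param first_year Year at which the linear time variable `t` is zero.
#'   Defaults to the earliest year of the series at fit time.
#' @param break_year Breakpoint: the post-period indicator is 1 strictly
#'   for years greater than `break_year`. Default 2014.
#' @param excluded_years Integer vector of calendar years removed from the
#'   fit. Default `break_year`. Use `integer(0)` to keep all years (the
#'   excluded year then joins the pre-break segment, since the indicator
#'   switches only after `break_year`).
#' @param family `"negative_binomial"` (NB2, dispersion estimated by
#'   maximum likelihood) or `"poisson"`.
#' @param ci_level Confidence level for Wald intervals, default 0.95.
#' @return An object of class `segmented_model_spec`.
#' @export
segmented_model_spec <- function(first_year = NULL,
                                 break_year = 2014L,
                                 excluded_years = break_year,
                                 family = c("negative_binomial", "poisson"),
                                 ci_level = 0.95) {
  family <- match.arg(family)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(list(first_year = if (is.null(first_year)) NULL
                              else as.integer(first_year),
                 break_year = as.integer(break_year),
                 excluded_years = as.integer(excluded_years),
                 family = family,
                 ci_level = ci_level),
            class = "segmented_model_spec")
}

#' Design matrix rows for the segmented count model
#'
#' For each retained year `y` the design carries three regressors:
#' `t = y - first_year` (annual trend), `I = 1` if `y > break_year`
#' (post-period indicator) and `X = (y - (break_year + 1)) * I`
#' (post-period slope change). Centering `X` at `break_year + 1` makes
#' `exp(beta2)` the ratio of the observed level in the first post-break
#' year to the level projected there from the pre-break linear trend, and
#' `exp(beta3)` the post- vs pre-break annual slope ratio.
#'
#' @param years Integer vector of calendar years in the series.
#' @param spec A [segmented_model_spec()].
#' @return A data.frame with columns `year`, `t`, `I`, `X`, one row per
#'   retained (non-excluded) year.
#' @export
#' @examples
#' build_design(2009:2019, segmented_model_spec())
build_design <- function(years, spec = segmented_model_spec()) {
  years <- as.integer(years)
  if (spec$break_year <= min(years) || spec$break_year >= max(years)) {
    stop("break_year must lie strictly inside the year range")
  }
  if (!all(spec$excluded_years %in% years)) {
    stop("excluded_years must be a subset of the series years")
  }
  first_year <- if (is.null(spec$first_year)) min(years) else spec$first_year
  keep <- !(years %in% spec$excluded_years)
  if (!any(keep)) stop("all years are excluded")
  y <- years[keep]
  i <- as.integer(y > spec$break_year)
  data.frame(year = y,
             t = y - first_year,
             I = i,
             X = (y - (spec$break_year + 1L)) * i)
}

#' Compute annual rates from numerator/denominator pairs
#'
#' @param series A data.frame with columns `year`, `numerator`,
#'   `denominator` (a `series` label column is carried through if present).
#' @param digits Decimal places for the reported rate (default 2, the
#'   conventional presentation precision; the unrounded ratio is used in
#'   all model fitting, which works from the raw counts).
#' @return The input with a `rate` column, `100 * numerator / denominator`
#'   rounded to `digits`.
#' @export
compute_yearly_rates <- function(series, digits = 2) {
  stopifnot(all(c("year", "numerator", "denominator") %in% names(series)))
  bad <- series$denominator <= 0
  if (any(bad)) {
    stop("zero or negative denominator in year(s): ",
         paste(series$year[bad], collapse = ", "))
  }
  if (any(series$numerator < 0)) stop("negative numerator")
  if (any(series$numerator > series$denominator)) {
    stop("numerator exceeds denominator in year(s): ",
         paste(series$year[series$numerator > series$denominator],
               collapse = ", "))
  }
  series$rate <- round(100 * series$numerator / series$denominator, digits)
  series
}

#' Fit a segmented count regression to an annual series
#'
#' Maximum-likelihood fit of `numerator ~ t + I + X` with offset
#' `log(denominator)`, using the design coding of [build_design()]. The
#' default family is NB2 (variance `mu + alpha * mu^2`, dispersion `alpha`
#' estimated by ML via [MASS::glm.nb()]). When the NB fit fails to
#' converge, or the estimated dispersion is below `1e-8` (the equidispersed
#' boundary, where the NB likelihood degenerates to Poisson), the model is
#' refit with a Poisson family and the result is flagged accordingly.
#' Confidence intervals are Wald intervals on the log scale,
#' `exp(beta +/- z * se)`.
#'
#' @param series Data.frame with `year`, `numerator`, `denominator`.
#' @param spec A [segmented_model_spec()].
#' @return An object of class `segmented_fit`: a list with elements
#'   `coefficients` (data.frame: term, estimate, se, irr, ci_low, ci_high,
#'   p_value, significant), `dispersion` (NB2 alpha; 0 for Poisson fits),
#'   `family` (family actually used), `requested_family`, `converged`,
#'   `loglik`, `spec`, `design` (design rows joined with counts) and
#'   `model` (the underlying glm object).
#' @export
#' @examples
#' ltot <- counts_to_series(annual_counts_fixture(), "ltot")
#' fit <- fit_segmented(ltot)
#' fit$coefficients
fit_segmented <- function(series, spec = segmented_model_spec()) {
  des <- build_design(series$year, spec)
  des <- merge(des, series[, c("year", "numerator", "denominator")],
               by = "year")
  des <- des[order(des$year), ]
  if (nrow(des) < 6) stop("need at least 6 retained years to fit")
  if (any(des$numerator < 0)) stop("negative numerator")
  if (any(des$denominator <= 0)) stop("non-positive denominator")

  fit_family <- spec$family
  model <- NULL
  if (fit_family == "negative_binomial") {
    model <- tryCatch(
      suppressWarnings(
        MASS::glm.nb(numerator ~ t + I + X + offset(log(denominator)),
                     data = des)),
      error = function(e) NULL)
    if (is.null(model) || !isTRUE(model$converged) ||
        (1 / model$theta) < 1e-8) {
      fit_family <- "poisson"
      model <- NULL
    }
  }
  if (is.null(model)) {
    model <- stats::glm(numerator ~ t + I + X + offset(log(denominator)),
                        family = stats::poisson(), data = des)
    if (!isTRUE(model$converged)) {
      stop("neither negative binomial nor Poisson fit converged; ",
           "series years: ", paste(des$year, collapse = ", "))
    }
  }

  sm <- summary(model)$coefficients
  z <- stats::qnorm(1 - (1 - spec$ci_level) / 2)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  p <- 2 * stats::pnorm(-abs(est / se))
  coefs <- data.frame(
    term = c("beta0", "beta1", "beta2", "beta3"),
    label = c("Intercept", "Time (beta1)", "Indicator (beta2)",
              "Interaction term (beta3)"),
    estimate = unname(est),
    se = unname(se),
    irr = unname(exp(est)),
    ci_low = unname(exp(est - z * se)),
    ci_high = unname(exp(est + z * se)),
    p_value = unname(p),
    significant = unname(p < 0.05),
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    dispersion = if (fit_family == "negative_binomial") 1 / model$theta
                 else 0,
    family = fit_family,
    requested_family = spec$family,
    converged = TRUE,
    loglik = as.numeric(stats::logLik(model)),
    spec = spec,
    design = des,
    model = model
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented %s fit (break %d; excluded: %s)\n",
              x$family, x$spec$break_year,
              if (length(x$spec$excluded_years) == 0) "none"
              else paste(x$spec$excluded_years, collapse = ", ")))
  tab <- x$coefficients
  tab$irr <- sprintf("%.3f (%.3f, %.3f)%s", tab$irr, tab$ci_low,
                     tab$ci_high, ifelse(tab$significant, "*", ""))
  print(tab[, c("label", "irr", "p_value")], row.names = FALSE)
  cat(sprintf("dispersion (alpha): %.3g  logLik: %.2f\n",
              x$dispersion, x$loglik))
  invisible(x)
}

#' Extract exponentiated coefficients from a segmented fit
#'
#' @param fit A `segmented_fit`.
#' @param terms Which terms to return (default the three trend terms).
#' @return Named numeric vector of incidence rate ratios.
#' @export
irr <- function(fit, terms = c("beta1", "beta2", "beta3")) {
  stopifnot(inherits(fit, "segmented_fit"))
  out <- fit$coefficients$irr[match(terms, fit$coefficients$term)]
  stats::setNames(out, terms)
}

#' Counterfactual projection of the pre-break trend
#'
#' Projects the rate (percent scale) that the pre-break linear trend alone
#' implies for the requested years: the indicator and interaction terms
#' are forced to zero so only the intercept and pre-break slope are used.
#'
#' @param fit A `segmented_fit`.
#' @param years Calendar years to project over.
#' @return Data.frame with `year` and `projected_rate` (percent).
#' @export
project_counterfactual <- function(fit, years) {
  stopifnot(inherits(fit, "segmented_fit"))
  first_year <- if (is.null(fit$spec$first_year)) min(fit$design$year)
                else fit$spec$first_year
  b <- fit$coefficients$estimate
  data.frame(year = years,
             projected_rate = 100 * exp(b[1] + b[2] * (years - first_year)))
}

#' Likelihood-ratio scan for a single structural break
#'
#' For each candidate break year, fits a segmented Poisson model (break at
#' that year, no years excluded) and compares it against the single-trend
#' Poisson model by a likelihood-ratio statistic (2 extra parameters). The
#' selected break maximises the statistic; the selection is flagged
#' non-significant when the maximum falls below the chi-squared 95th
#' percentile on 2 degrees of freedom.
#'
#' @param series Data.frame with `year`, `numerator`, `denominator`.
#' @param candidates Candidate break years; defaults to all years with at
#'   least 3 years on each side.
#' @return A list of class `breakpoint_scan` with the statistic `table`
#'   (year, lr_stat), `selected_year`, `significant` and `statistic_kind`.
#' @export
structural_break_scan <- function(series, candidates = NULL) {
  years <- sort(series$year)
  if (is.null(candidates)) {
    candidates <- years[years >= years[4] & years <= years[length(years) - 3]]
  }
  ok <- vapply(candidates, function(b) {
    sum(years <= b) >= 3 && sum(years > b) >= 3
  }, logical(1))
  if (!all(ok)) {
    stop("candidates need >= 3 years on each side: ",
         paste(candidates[!ok], collapse = ", "))
  }
  null_model <- stats::glm(
    numerator ~ I(year - min(year)) + offset(log(denominator)),
    family = stats::poisson(), data = series)
  ll0 <- as.numeric(stats::logLik(null_model))
  stats_lr <- vapply(candidates, function(b) {
    sp <- segmented_model_spec(break_year = b, excluded_years = integer(0),
                               family = "poisson")
    f <- fit_segmented(series, sp)
    2 * (f$loglik - ll0)
  }, numeric(1))
  sel <- candidates[which.max(stats_lr)]
  structure(list(
    table = data.frame(year = candidates, lr_stat = stats_lr),
    selected_year = sel,
    significant = max(stats_lr) > stats::qchisq(0.95, df = 2),
    statistic_kind = "LR: segmented vs single-trend Poisson (df = 2)"
  ), class = "breakpoint_scan")
}

#' @export
print.breakpoint_scan <- function(x, ...) {
  cat("Structural break scan —", x$statistic_kind, "\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: %d (%s)\n", x$selected_year,
              if (x$significant) "significant" else "non-significant"))
  invisible(x)
}

#' Sensitivity fits for a segmented series
#'
#' Returns the two standard robustness checks: (a) the fit with the
#' breakpoint year retained in the likelihood (it joins the pre-break
#' segment, since the post-period indicator switches only strictly after
#' the break), and (b) the Poisson-family fit with the default exclusion.
#'
#' @param series Data.frame with `year`, `numerator`, `denominator`.
#' @param spec A [segmented_model_spec()].
#' @return List with elements `include_break_year` and `poisson`, each a
#'   `segmented_fit`.
#' @export
run_sensitivity <- function(series, spec = segmented_model_spec()) {
  spec_incl <- spec
  spec_incl$excluded_years <- integer(0)
  spec_pois <- spec
  spec_pois$family <- "poisson"
  list(include_break_year = fit_segmented(series, spec_incl),
       poisson = fit_segmented(series, spec_pois))
}

#' Plot observed rates, fitted segments and the counterfactual projection
#'
#' @param series Data.frame with `year`, `numerator`, `denominator` (rates
#'   recomputed internally).
#' @param fit Optional `segmented_fit` for the same series; when supplied,
#'   fitted segment rates and the pre-break counterfactual are overlaid.
#' @return A ggplot object.
#' @export
plot_trends <- function(series, fit = NULL) {
  series <- compute_yearly_rates(series)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = year, y = rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(x = "Year", y = "Rate (%)")
  if (!is.null(fit)) {
    des <- fit$design
    des$fitted_rate <- 100 * stats::fitted(fit$model) / des$denominator
    proj <- project_counterfactual(fit, series$year)
    p <- p +
      ggplot2::geom_line(data = des,
                         ggplot2::aes(y = fitted_rate, group = I),
                         colour = "firebrick") +
      ggplot2::geom_line(data = proj,
                         ggplot2::aes(y = projected_rate),
                         colour = "grey40", linetype = "dashed")
  }
  p
}
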