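flat_series <- function(rate = 0.1, den = 1e6, years = 2009:2019) {
  data.frame(series = "flat", year = years,
             numerator = as.integer(rate * den), denominator = den)
}

test_that("yearly rate arithmetic matches the published worked examples", {
  s <- data.frame(year = 2009, numerator = c(31905, 1690, 0),
                  denominator = c(254066, 31905, 1000))
  out <- compute_yearly_rates(s)
  expect_equal(out$rate, c(12.56, 5.30, 0.00))
  expect_error(compute_yearly_rates(
    data.frame(year = 2009, numerator = 1, denominator = 0)), "2009")
})

test_that("design coding anchors time, indicator and interaction correctly", {
  d <- build_design(2009:2019, segmented_model_spec())
  expect_false(2014 %in% d$year)
  expect_equal(unlist(d[d$year == 2009, c("t", "I", "X")]),
               c(t = 0, I = 0, X = 0))
  expect_equal(unlist(d[d$year == 2015, c("t", "I", "X")]),
               c(t = 6, I = 1, X = 0))
  expect_equal(unlist(d[d$year == 2019, c("t", "I", "X")]),
               c(t = 10, I = 1, X = 4))
  expect_error(build_design(2009:2013, segmented_model_spec()), "inside")
})

test_that("a perfectly flat series yields unit rate ratios", {
  fit <- fit_segmented(flat_series())
  expect_equal(unname(irr(fit)), rep(1, 3), tolerance = 1e-8)
})

test_that("offsets make the model a rate model", {
  s <- counts_to_series(annual_counts_fixture(), "ltot")
  f1 <- fit_segmented(s)
  s2 <- s
  s2$denominator <- s2$denominator * 10
  f2 <- fit_segmented(s2)
  expect_equal(irr(f1), irr(f2), tolerance = 1e-8)
  expect_equal(f2$coefficients$estimate[1],
               f1$coefficients$estimate[1] - log(10), tolerance = 1e-6)
})

test_that("shifting the time origin changes only the intercept", {
  s <- counts_to_series(annual_counts_fixture(), "ltot")
  f1 <- fit_segmented(s, segmented_model_spec(first_year = 2009))
  f2 <- fit_segmented(s, segmented_model_spec(first_year = 2000))
  expect_equal(irr(f1), irr(f2), tolerance = 1e-7)
  expect_false(isTRUE(all.equal(f1$coefficients$estimate[1],
                                f2$coefficients$estimate[1])))
})

test_that("negative binomial and Poisson agree on equidispersed counts", {
  off <- stats::setNames(rep(5e5, 11), 2009:2019)
  s <- generate_counts_from_model(c(-2, log(0.97), log(1.03), log(1.02)),
                                  off, dispersion = 0, seed = 3)
  s$series <- "sim"
  f_nb <- fit_segmented(s, segmented_model_spec(family = "negative_binomial"))
  f_po <- fit_segmented(s, segmented_model_spec(family = "poisson"))
  expect_equal(f_nb$coefficients$estimate, f_po$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("counterfactual projection obeys its closed-form identities", {
  s <- counts_to_series(annual_counts_fixture(), "ltot")
  fit <- fit_segmented(s)
  b <- fit$coefficients$estimate
  proj <- project_counterfactual(fit, c(2009, 2015))
  expect_equal(proj$projected_rate[1], 100 * exp(b[1]), tolerance = 1e-10)
  # fitted 2015 rate over projected 2015 rate equals exp(beta2) exactly:
  # at 2015 the design row is (t = 6, I = 1, X = 0)
  fitted_2015 <- 100 * exp(b[1] + b[2] * 6 + b[3])
  expect_equal(fitted_2015 / proj$projected_rate[2], exp(b[3]),
               tolerance = 1e-10)
  # the published L-TOT fit implies projected 2015 below observed 2015
  expect_gt(fitted_2015, proj$projected_rate[2])
})

test_that("the break scan recovers a planted break and flags flat series", {
  off <- stats::setNames(rep(1e5, 13), 2007:2019)
  hits <- 0
  for (seed in 1:20) {
    s <- generate_counts_from_model(c(-2, log(1.00), log(1.35), log(1.12)),
                                    off, dispersion = 0, break_year = 2013,
                                    seed = seed)
    s$series <- "sim"
    scan <- structural_break_scan(s)
    hits <- hits + (scan$selected_year == 2013)
  }
  expect_gte(hits, 19)  # planted break found in >=95% of runs

  flat <- flat_series(years = 2007:2019)
  scan_flat <- structural_break_scan(flat)
  expect_false(scan_flat$significant)
  expect_lt(max(scan_flat$table$lr_stat), 1e-6)
})

test_that("simulated-count means and dispersion match the generating model", {
  off <- stats::setNames(rep(1e6, 11), 2009:2019)
  s <- generate_counts_from_model(c(-2, 0, 0, 0), off, dispersion = 0,
                                  seed = 10)
  expect_equal(attr(s, "mu"), rep(1e6 * exp(-2), 11))
  expect_true(all(abs(s$numerator - 1e6 * exp(-2)) <
                    3 * sqrt(1e6 * exp(-2))))
  # equidispersion: variance/mean ratio near 1 across replicates
  reps <- vapply(1:1000, function(i) {
    generate_counts_from_model(c(-2, 0, 0, 0),
                               stats::setNames(rep(1e4, 6), 2012:2017),
                               dispersion = 0, break_year = 2014,
                               seed = i)$numerator[1]
  }, numeric(1))
  ratio <- stats::var(reps) / mean(reps)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("sensitivity fits pair the include-break and Poisson variants", {
  s <- counts_to_series(annual_counts_fixture(), "discontinuer")
  sens <- run_sensitivity(s)
  expect_equal(nrow(sens$include_break_year$design), 11)
  expect_true(2014 %in% sens$include_break_year$design$year)
  expect_equal(sens$include_break_year$design$I[
    sens$include_break_year$design$year == 2014], 0)
  expect_equal(sens$poisson$family, "poisson")
})

test_that("trend plot builds from a series with and without a fit", {
  s <- counts_to_series(annual_counts_fixture(), "ltot")
  expect_s3_class(plot_trends(s), "ggplot")
  expect_s3_class(plot_trends(s, fit_segmented(s)), "ggplot")
})
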