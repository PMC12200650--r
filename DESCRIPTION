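Package: opioidtrends
Title: Phenotyping and Segmented Trend Analysis of Long-Term Opioid
    Therapy in Primary-Care Prescription Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenotypes longitudinal primary-care prescription records into
    incident opioid users (new-user design with a 12-month washout),
    long-term opioid therapy (L-TOT) episodes (>=3 prescriptions within 90
    days or >=90 supply days in the first follow-up year, excluding the
    initial 30 days) and L-TOT discontinuation events (>=180 opioid-free
    days). Cleans prescription issues into daily oral morphine milligram
    equivalents, assembles annual numerator/denominator rate series, and
    fits segmented negative-binomial interrupted-time-series models with a
    log-denominator offset around a 2014 prescribing-policy breakpoint,
    with Poisson sensitivity fits and a structural-break scan. Ships a
    synthetic generator of CPRD-Aurum-like patient, prescription and
    diagnosis tables with planted ground-truth labels so the whole
    pipeline is testable without access to restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
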