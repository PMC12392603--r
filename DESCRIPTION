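Package: fitvalid
Title: External Validation of FIT-Based Colorectal Cancer Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to externally validate risk prediction models that combine a
    faecal immunochemical test (FIT) with demographics and blood counts for
    triaging symptomatic primary-care patients with suspected colorectal
    cancer. Implements the matched-sensitivity referral-reduction comparison
    against the conventional FIT >= 10 ug/g referral rule, discrimination
    (c-statistic, Davis-Goadrich precision-recall interpolation, average
    precision, test-reduction curves), calibration (observed/expected ratio,
    logistic intercept and slope, LOWESS curves), three recalibration methods,
    decision-curve net benefit, bootstrap percentile confidence intervals, and
    Wilson intervals for monthly positivity series. Ships a synthetic cohort
    generator that emulates a zero-inflated, heavy-tailed FIT distribution
    with temporal case-mix drift so the whole pipeline can be exercised and
    tested without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
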