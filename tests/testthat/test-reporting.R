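test_that("2x2 chi-square equals the expected-counts formulation", {
  set.seed(81)
  for (i in 1:25) {
    tab <- matrix(sample(5:500, 4), 2)
    res <- pearson_chi2_2x2(tab)
    O <- tab
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
    # and the standard library agrees without continuity correction
    expect_equal(res$statistic,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)))
  }
  expect_error(pearson_chi2_2x2(0, 0, 5, 5),
               class = "fitvalid_degenerate_error")
})

test_that("Mann-Whitney U: hand enumeration and extremes", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 4)
  # x1 entirely above x0: U = m*n
  expect_equal(mann_whitney_u(1:5, 6:9)$U, 20)
  # ties counted 1/2 through mid-ranks: pairs 2>1, 2=2 (1/2), 3>1, 3>2
  expect_equal(mann_whitney_u(c(1, 2), c(2, 3))$U, 3.5)
  expect_error(mann_whitney_u(numeric(0), 1),
               class = "fitvalid_domain_error")
  # exchangeable samples: mean U near mn/2
  set.seed(82)
  u <- replicate(300, mann_whitney_u(rnorm(12), rnorm(15))$U)
  m <- 15; n0 <- 12
  se <- sqrt(m * n0 * (m + n0 + 1) / 12)
  expect_lt(abs(mean(u) - m * n0 / 2), 3 * se / sqrt(300))
})

test_that("U agrees with the standard rank-sum implementation", {
  set.seed(83)
  x0 <- round(rnorm(40, 50, 10)); x1 <- round(rnorm(30, 55, 10))
  expect_equal(mann_whitney_u(x0, x1)$U,
               unname(suppressWarnings(wilcox.test(x1, x0)$statistic)))
})

test_that("monthly series counts, suppresses and bounds positivity", {
  set.seed(84)
  coh <- generate_cohort(synthetic_params(
    n_patients = 3000, start_month = "2022-01", end_month = "2022-06",
    seed = 51))
  tr <- monthly_trend(coh)
  expect_equal(sum(tr$n_tests), 3000)
  ok <- !tr$suppressed
  expect_equal(tr$positivity[ok], (tr$n_positive / tr$n_tests)[ok])
  expect_true(all(tr$lower[ok] <= tr$positivity[ok] &
                    tr$positivity[ok] <= tr$upper[ok]))
  # months with < 10 positives carry no proportion
  few <- data.frame(fit_date = as.Date("2020-01-15") + 0:8,
                    fit_value = rep(100, 9))
  tr2 <- monthly_trend(few)
  expect_true(tr2$suppressed)
  expect_true(is.na(tr2$positivity))
})

test_that("device grouping splits the series", {
  coh <- generate_cohort(synthetic_params(
    n_patients = 2000, start_month = "2021-05", end_month = "2021-09",
    seed = 52))
  tr <- monthly_trend(coh, by_device = TRUE)
  expect_true("device" %in% names(tr))
  expect_equal(sum(tr$n_tests), 2000)
})

test_that("volume-positivity regression: collinear, null and ramp cases", {
  ser <- data.frame(month = sprintf("2022-%02d", 1:8),
                    n_tests = seq(400, 1100, 100),
                    n_positive = 50, suppressed = FALSE)
  ser$positivity <- 0.05 + 0.0001 * ser$n_tests   # perfectly collinear
  reg <- suppressWarnings(volume_positivity_regression(ser))
  expect_equal(reg$r_squared, 1)
  # independent series: slope p-values roughly uniform under the null
  set.seed(85)
  ps <- replicate(200, {
    s <- data.frame(month = sprintf("m%02d", 1:12),
                    n_tests = rpois(12, 800),
                    positivity = runif(12, .08, .16), suppressed = FALSE)
    volume_positivity_regression(s)$p_slope
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
  expect_error(volume_positivity_regression(ser[1:2, ]),
               class = "fitvalid_insufficient_data_error")
})

test_that("drifting scenario shows rising positivity and a positive slope", {
  coh <- generate_cohort(scenario_sixperiod(seed = 77))
  tr <- monthly_trend(coh)
  ok <- !tr$suppressed
  # positivity trend across the study: later months higher on average
  first_year <- tr$positivity[ok & tr$month <= "2018-12"]
  last_year <- tr$positivity[ok & tr$month >= "2022-07"]
  expect_gt(mean(last_year), mean(first_year))
  reg <- volume_positivity_regression(tr, c("2020-07", "2023-06"))
  expect_gt(reg$slope, 0)
})

test_that("report bundle is complete, consistent and deterministic", {
  p <- scenario_sixperiod(n_patients = 12000, seed = 90)
  coh <- generate_cohort(p)
  risk <- true_risk(p$model, coh)
  rep1 <- suppressMessages(build_report(coh, risk,
                                        external_threshold_pct = 0.64))
  rep2 <- suppressMessages(build_report(coh, risk,
                                        external_threshold_pct = 0.64))
  expect_identical(rep1$thresholds, rep2$thresholds)
  # six period rows plus the all-data row, counts matching the generator
  expect_equal(nrow(rep1$periods), 7)
  expect_equal(rep1$periods$n[rep1$periods$period == "All data"], nrow(coh))
  per <- rep1$periods[rep1$periods$period != "All data", ]
  expect_equal(sort(per$n),
               sort(as.vector(table(coh$period))))
  # threshold table has local-current, external and local-previous modes
  expect_setequal(unique(rep1$thresholds$mode),
                  c("local current", "external", "local previous"))
  expect_equal(sum(rep1$thresholds$mode == "local previous"), 5)
  # calibration contains the FIT-spline comparator with O/E 1 in-sample
  spline_rows <- rep1$calibration[rep1$calibration$model == "FIT-spline", ]
  expect_true(all(abs(spline_rows$oe_ratio - 1) < 1e-6))
  # model scored with its generator discriminates better than FIT alone
  dis <- rep1$discrimination[rep1$discrimination$period == "All data", ]
  expect_gt(dis$average_precision[dis$model == "risk-model"],
            dis$average_precision[dis$model == "FIT test"])
  # files written
  dir <- tempfile()
  write_report(rep1, dir)
  expect_true(all(file.exists(file.path(
    dir, c("periods.csv", "thresholds.csv", "calibration.csv",
           "discrimination.csv")))))
  unlink(dir, recursive = TRUE)
})
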