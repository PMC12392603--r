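test_that("calibration summary reproduces the O/E arithmetic", {
  y <- rep(c(1, 0), c(128, 9872))
  p <- plogis(qlogis(0.0084) + rnorm(10000, 0, 0.3))
  p <- p * 0.0084 / mean(p)            # pin the mean risk at 0.84%
  cs <- calibration_summary(y, p)
  expect_equal(cs$event_rate, 1.28)
  expect_equal(round(cs$oe_ratio, 2), 1.52)
  # exact identity between the three summary fields
  expect_equal(cs$oe_ratio * cs$mean_risk, cs$event_rate, tolerance = 1e-12)
})

test_that("parameter recovery: outcomes drawn from p look calibrated", {
  set.seed(21)
  n <- 30000
  p <- plogis(rnorm(n, -4, 1.2))
  y <- rbinom(n, 1, p)
  cs <- calibration_summary(y, p)
  se_oe <- sqrt(mean(p) * (1 - mean(p)) / n) / mean(p)
  expect_lt(abs(cs$oe_ratio - 1), 3 * se_oe)
  expect_lt(abs(cs$logistic_intercept), 0.3)
  expect_lt(abs(cs$logistic_slope - 1), 0.1)
})

test_that("constant predictions are flagged degenerate with exact O/E", {
  y <- rep(c(1, 0), c(10, 990))
  expect_warning(cs <- calibration_summary(y, rep(0.01, 1000)),
                 "constant")
  expect_equal(cs$oe_ratio, 1)
  expect_true(cs$degenerate)
  expect_true(is.na(cs$logistic_slope))
})

test_that("calibration summary rejects out-of-range probabilities", {
  expect_error(calibration_summary(c(0, 1), c(0, 0.5)),
               class = "fitvalid_domain_error")
})

test_that("LOWESS curve tracks the diagonal for calibrated predictions", {
  set.seed(22)
  n <- 5000
  p <- plogis(rnorm(n, -2.5, 1))
  y <- rbinom(n, 1, p)
  curve <- lowess_calibration_curve(y, p)
  mid <- curve$p > quantile(p, .2) & curve$p < quantile(p, .8)
  expect_lt(median(abs(curve$observed[mid] - curve$p[mid])), 0.03)
  expect_true(all(curve$observed >= 0 & curve$observed <= 1))
})

test_that("LOWESS curve is flat at prevalence when p carries no signal", {
  set.seed(23)
  y <- rbinom(3000, 1, 0.2)
  p <- runif(3000, 0.05, 0.6)
  curve <- lowess_calibration_curve(y, p)
  expect_lt(max(abs(curve$observed - 0.2)), 0.1)
})

test_that("systematic under-prediction lifts the curve above the diagonal", {
  set.seed(24)
  p <- runif(4000, 0.05, 0.55)
  y <- rbinom(4000, 1, pmin(1.5 * p, 1))
  curve <- lowess_calibration_curve(y, p)
  mid <- curve$p > 0.1 & curve$p < 0.5
  expect_true(mean(curve$observed[mid] > curve$p[mid]) > 0.95)
  expect_error(lowess_calibration_curve(y[1:10], p[1:10]),
               class = "fitvalid_parameter_error")
})

test_that("FIT scaling: identity, arithmetic, and share matching", {
  expect_equal(as.numeric(recalibrate_fit_scale(c(3, 6, 20), k = 1)),
               c(3, 6, 20))
  expect_equal(as.numeric(recalibrate_fit_scale(c(3, 6, 20), k = 2)),
               c(6, 12, 40))
  expect_error(recalibrate_fit_scale(1:3, k = -1),
               class = "fitvalid_domain_error")
  # move positivity up to a reference share on a less zero-heavy cohort
  coh <- generate_cohort(synthetic_params(n_patients = 20000, seed = 31,
                                          fit_zero_mass = 0.65))
  k <- estimate_fit_scale(coh$fit_value, target_share = 0.224)
  scaled <- recalibrate_fit_scale(coh$fit_value, k = k)
  expect_lt(abs(mean(scaled >= 10) - 0.224), 0.005)
  # independent bisection oracle over the step function of k
  share <- function(kk) mean(coh$fit_value * kk >= 10)
  lo <- 1e-3; hi <- 1e3
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (share(mid) < 0.224) lo <- mid else hi <- mid
  }
  expect_lte(abs(share(k) - 0.224), abs(share(hi) - 0.224) + 1e-12)
  # an unreachable target saturates at the share of nonzero values
  k_max <- estimate_fit_scale(coh$fit_value, target_share = 0.99)
  expect_equal(mean(coh$fit_value * k_max >= 10), mean(coh$fit_value > 0))
})

test_that("quantile mapping: identity, closed form, zero inflation", {
  set.seed(26)
  # ref = source: order statistics reproduced
  x <- sort(rlnorm(200, 2, 1))
  ref <- reference_fit_distribution(sample = x)
  expect_equal(sort(recalibrate_fit_quantile(x, ref)), sort(x),
               tolerance = 1e-12)
  # uniform [0,1] source to uniform [0,10] reference: 0.25 -> 2.5
  src <- seq(0.0005, 0.9995, length.out = 1000)
  refu <- reference_fit_distribution(values = seq(0.01, 10, length.out = 1000),
                                     cum_prob = seq(0.001, 1, length.out = 1000))
  mapped <- recalibrate_fit_quantile(src, refu)
  expect_equal(mapped[which.min(abs(src - 0.25))], 2.5, tolerance = 0.05)
  # zero-inflated source: all zeros map to one reference quantile
  z <- c(rep(0, 780), rlnorm(220, 3, 1))
  refn <- reference_fit_synthetic_derivation()
  mz <- recalibrate_fit_quantile(z, refn)
  expect_equal(length(unique(mz[z == 0])), 1L)
  # mid-rank convention verified by brute-force rank computation
  u0 <- mean(rank(z)[z == 0]) / length(z)
  expect_equal(unique(mz[z == 0]),
               approx(refn$cum_prob, refn$value, xout = u0, rule = 2)$y)
})

test_that("quantile-mapped values match reference quantiles in distribution", {
  set.seed(27)
  src <- rlnorm(5000, 1, 2)
  ref_sample <- rlnorm(5000, 2.5, 1)
  ref <- reference_fit_distribution(sample = ref_sample)
  mapped <- recalibrate_fit_quantile(src, ref)
  qs <- seq(0.1, 0.9, 0.1)
  expect_lt(max(abs(quantile(mapped, qs) - quantile(ref_sample, qs)) /
                  quantile(ref_sample, qs)), 0.1)
})

test_that("logistic recalibration is a fixed point on calibrated data", {
  set.seed(28)
  n <- 20000
  p <- plogis(rnorm(n, -3.5, 1))
  y <- rbinom(n, 1, p)
  f <- logistic_recalibration(y, p)
  cf <- attr(f, "coefficients")
  expect_lt(abs(cf["intercept"]), 0.15)
  expect_lt(abs(cf["slope"] - 1), 0.05)
  expect_lt(max(abs(f(p) - p)), 0.05)
  # idempotence up to estimation noise
  f2 <- logistic_recalibration(y, f(p))
  cf2 <- attr(f2, "coefficients")
  expect_lt(abs(cf2["intercept"]), 1e-6)
  expect_lt(abs(cf2["slope"] - 1), 1e-6)
})

test_that("halved probabilities recalibrate back to O/E near 1", {
  set.seed(29)
  n <- 30000
  truth <- plogis(rnorm(n, -3.2, 1))
  y <- rbinom(n, 1, truth)
  p_half <- truth / 2
  f <- logistic_recalibration(y, p_half)
  cs <- calibration_summary(y, f(p_half))
  se_oe <- sqrt(mean(truth) * (1 - mean(truth)) / n) / mean(truth)
  expect_lt(abs(cs$oe_ratio - 1), 3 * se_oe)
  expect_error(logistic_recalibration(y, rep(0.1, n)),
               class = "fitvalid_degenerate_error")
})

test_that("FIT-spline comparator is calibrated in-sample and monotone", {
  set.seed(30)
  coh <- generate_cohort(synthetic_params(n_patients = 20000, seed = 33))
  spl <- fit_spline_model(coh$fit_value, coh$crc)
  p <- predict(spl, coh$fit_value)
  cs <- calibration_summary(coh$crc, p)
  expect_equal(cs$oe_ratio, 1, tolerance = 1e-6)  # in-sample logistic fit
  # nondecreasing predicted risk along the FIT grid (monotone data)
  grid <- predict(spl, seq(0, 400, by = 5))
  expect_true(all(diff(grid) > -1e-6))
  # constant FIT degrades to the prevalence
  spl0 <- fit_spline_model(rep(5, 200), rep(c(1, 0), c(20, 180)))
  expect_equal(unique(predict(spl0, c(0, 10))), 0.1, tolerance = 1e-6)
})
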