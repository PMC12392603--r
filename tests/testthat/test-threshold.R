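test_that("FIT positivity is inclusive at the threshold", {
  expect_equal(fit_positive(c(10, 9.9, 400, 0)), c(1L, 0L, 1L, 0L))
})

test_that("matched threshold reproduces the worked 8-patient example", {
  s <- toy_scores()
  thr <- matched_sensitivity_threshold(s)
  expect_equal(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "target_tp"), 2L)
  cmp <- referral_reduction(s, as.numeric(thr))
  expect_equal(cmp$n_pos_model, 2L)
  expect_equal(cmp$n_pos_fit, 4L)
  expect_equal(cmp$pct_reduction, -50)
  expect_equal(cmp$delta_sens, 0)
  expect_equal(cmp$n_missed_or_gained, 0L)
})

test_that("a risk monotone in FIT reproduces the FIT positive set exactly", {
  set.seed(10)
  fit <- c(rep(0, 60), rlnorm(40, 3, 1.2))
  fit <- censor_fit(fit)
  y <- rbinom(100, 1, ifelse(fit >= 10, 0.4, 0.02))
  # the lowest FIT-positive value belongs to a cancer, so the matched
  # threshold cannot shed boundary non-cancers below the first case
  y[which(fit == min(fit[fit >= 10]))] <- 1
  risk <- plogis(-4 + 0.8 * log(fit + 1))  # strictly increasing transform
  s <- risk_scores(risk, fit, y)
  thr <- suppressMessages(matched_sensitivity_threshold(s))
  cmp <- referral_reduction(s, as.numeric(thr))
  expect_equal(cmp$n_pos_model, cmp$n_pos_fit)
  expect_equal(cmp$pct_reduction, 0)
  expect_equal(cmp$delta_sens, 0)
})

test_that("all cancers on one risk value force that threshold", {
  s <- risk_scores(risk = c(.5, .5, .5, .9, .1),
                   fit = c(20, 30, 40, 5, 0),
                   y = c(1, 1, 1, 0, 0))
  expect_equal(as.numeric(matched_sensitivity_threshold(s)), 0.5)
})

test_that("matched threshold errors when FIT detects nothing", {
  s <- risk_scores(risk = c(.9, .1), fit = c(0, 5), y = c(1, 0))
  expect_error(matched_sensitivity_threshold(s),
               class = "fitvalid_degenerate_error")
})

test_that("tie relaxation never captures fewer cancers than FIT", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    # coarse risk grid forces ties
    s <- risk_scores(risk = sample(seq(.1, .9, .2), n, replace = TRUE),
                     fit = sample(c(0, 0, 5, 12, 50, 200), n, replace = TRUE),
                     y = rbinom(n, 1, .4))
    if (sum(s$y) == 0 || all(s$y == 1)) next
    if (sum(s$y == 1 & s$fit >= 10) == 0) next
    thr <- suppressMessages(matched_sensitivity_threshold(s))
    expect_gte(attr(thr, "tp"), attr(thr, "target_tp"))
    expect_equal(as.numeric(thr), oracle_matched_threshold(s))
  }
})

test_that("referral reduction reproduces the published worked example", {
  # 100,000 tests: 21,383 model-positive vs 22,427 FIT-positive
  n <- 100000
  risk <- rep(c(0.9, 0.1), c(21383, n - 21383))
  fit <- rep(c(50, 0), c(22427, n - 22427))
  y <- rep(c(1, 0), c(300, n - 300))
  cmp <- referral_reduction(risk_scores(risk, fit, y), threshold = 0.5)
  expect_equal(round(cmp$pct_reduction, 1), -4.7)
  expect_equal(cmp$n_pos_model, 21383L)
  expect_equal(cmp$pos_per_1000_fit, 224.27)
})

test_that("identical classifications give an all-zero comparison", {
  set.seed(4)
  s <- random_scores(400)
  fitlike <- plogis(log(s$fit + 1) - 2.5)  # monotone transform of fit
  s2 <- risk_scores(fitlike, s$fit, s$y)
  thr10 <- min(fitlike[s$fit >= 10])
  cmp <- referral_reduction(s2, thr10)
  expect_equal(cmp$pct_reduction, 0)
  expect_equal(cmp$delta_sens, 0)
  expect_equal(cmp$n_missed_or_gained, 0L)
})

test_that("comparison fields satisfy their defining identities", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_scores(300)
    if (sum(s$y == 1 & s$fit >= 10) == 0) next
    thr <- suppressMessages(matched_sensitivity_threshold(s))
    cmp <- referral_reduction(s, as.numeric(thr))
    expect_equal(cmp$pct_reduction,
                 (cmp$n_pos_model - cmp$n_pos_fit) / cmp$n_pos_fit * 100)
    expect_equal(cmp$pos_per_1000_model, cmp$n_pos_model / nrow(s) * 1000)
    expect_equal(cmp$delta_sens, cmp$sens_model - cmp$sens_fit)
    # PPV identity at equal TP counts
    tp <- cmp$n_cancers_total * cmp$sens_model / 100
    if (cmp$n_missed_or_gained == 0L && tp > 0) {
      ppv_m <- tp / cmp$n_pos_model
      ppv_f <- tp / cmp$n_pos_fit
      expect_equal(cmp$pct_reduction, (ppv_f / ppv_m - 1) * 100)
    }
  }
})

test_that("counts are invariant under strictly increasing risk transforms", {
  set.seed(6)
  s <- random_scores(250)
  thr <- suppressMessages(matched_sensitivity_threshold(s))
  cmp <- referral_reduction(s, as.numeric(thr))
  s2 <- risk_scores(plogis(qlogis(s$risk) * 2 + 1), s$fit, s$y)
  thr2 <- suppressMessages(matched_sensitivity_threshold(s2))
  cmp2 <- referral_reduction(s2, as.numeric(thr2))
  count_cols <- c("n_pos_model", "n_pos_fit", "pct_reduction", "sens_model",
                  "sens_fit", "delta_sens", "n_missed_or_gained")
  expect_equal(cmp[count_cols], cmp2[count_cols], ignore_attr = TRUE)
})

test_that("external threshold evaluation handles degenerate extremes", {
  s <- toy_scores()
  hi <- external_threshold_evaluation(s, 99.99)
  expect_equal(hi$n_pos_model, 0L)
  expect_equal(hi$sens_model, 0)
  lo <- external_threshold_evaluation(s, 0.65)  # percent scale: 0.0065
  expect_equal(lo$n_pos_model, 8L)
  expect_error(external_threshold_evaluation(s, 0),
               class = "fitvalid_domain_error")
  expect_error(external_threshold_evaluation(s, 100),
               class = "fitvalid_domain_error")
})

test_that("prospective simulation applies the previous period's threshold", {
  set.seed(8)
  s <- random_scores(500)
  # two identical periods: prospective equals local-current of period 2
  res <- prospective_simulation(list(p1 = s, p2 = s))
  thr <- suppressMessages(matched_sensitivity_threshold(s))
  local <- referral_reduction(s, as.numeric(thr))
  expect_equal(res$pct_reduction, local$pct_reduction)
  expect_equal(res$period, "p2")
  expect_equal(res$threshold_period, "p1")
  # a period without FIT-detected cancers is skipped with a warning
  s0 <- risk_scores(c(.9, .1, .2), c(0, 0, 5), c(1, 0, 0))
  expect_warning(res2 <- prospective_simulation(list(a = s0, b = s, c = s)),
                 "skipped")
  expect_equal(res2$period, "c")
  expect_error(prospective_simulation(list(s)),
               class = "fitvalid_parameter_error")
})

test_that("stationary prospective delta-sensitivity stays near zero", {
  set.seed(9)
  periods <- lapply(1:3, function(i) random_scores(4000))
  names(periods) <- c("t1", "t2", "t3")
  res <- suppressMessages(prospective_simulation(periods))
  # same generating process: sensitivity differences are sampling noise
  ncase <- vapply(periods[-1], function(s) sum(s$y), numeric(1))
  se <- 100 * sqrt(0.9 * 0.1 / ncase)   # binomial scale of a ~90% sensitivity
  expect_true(all(abs(res$delta_sens) < 3 * se))
})
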