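# Descriptive statistics, monthly trend analyses and report assembly.

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction:
#' `n * (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, 1 degree of freedom. This
#' equals the expected-counts formulation `sum((O - E)^2 / E)`.
#'
#' @param a,b,c,d cell counts of the (group x outcome) table, or pass a
#'   2x2 matrix as `a`.
#' @return list with `statistic`, `df` (1) and `p_value`.
#' @examples
#' pearson_chi2_2x2(20972, 371, 29846, 288)$statistic  # 60.5
#' @export
pearson_chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) <= 0) {
    fv_stop("pearson_chi2_2x2: counts must be non-negative with positive total",
            "fitvalid_domain_error")
  }
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    fv_stop("pearson_chi2_2x2: degenerate table (zero margin)",
            "fitvalid_degenerate_error")
  }
  n <- sum(counts)
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Mann-Whitney U statistic
#'
#' U for the comparison of `x1` against `x0`: the number of pairs with
#' `x1 > x0`, ties counted 1/2, computed through mid-ranks. Reported with
#' the group medians, as location comparisons in descriptive tables usually
#' are.
#'
#' @param x0 reference group sample.
#' @param x1 comparison group sample.
#' @return list with `U`, `n0`, `n1`, `median0`, `median1`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$U  # 4
#' @export
mann_whitney_u <- function(x0, x1) {
  if (length(x0) == 0L || length(x1) == 0L) {
    fv_stop("mann_whitney_u: both samples must be nonempty",
            "fitvalid_domain_error")
  }
  n1 <- length(x1)
  r <- rank(c(x1, x0))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = U, n0 = length(x0), n1 = n1,
       median0 = stats::median(x0), median1 = stats::median(x1))
}

#' Monthly FIT testing series
#'
#' Per calendar month: number of tests, number of FIT-positive tests,
#' positivity with a Wilson interval, and a suppression flag for months
#' with fewer than `min_positives` positive events (no proportion is
#' reported for those, mirroring small-count reporting rules). Optionally
#' grouped by the sampling-device flag.
#'
#' @param cohort cohort `data.frame` with `fit_date`, `fit_value` and
#'   optionally `device`.
#' @param fit_threshold positivity threshold, default 10.
#' @param min_positives suppression threshold, default 10.
#' @param by_device logical; split the series by the device flag.
#' @param level Wilson interval coverage, percent.
#' @return `data.frame` with `month`, (`device`,) `n_tests`, `n_positive`,
#'   `positivity`, `lower`, `upper`, `suppressed`.
#' @export
monthly_trend <- function(cohort, fit_threshold = 10, min_positives = 10,
                          by_device = FALSE, level = 95) {
  check_columns(cohort, c("fit_date", "fit_value"), "monthly_trend")
  groups <- if (by_device) {
    check_columns(cohort, "device", "monthly_trend")
    split(cohort, cohort$device)
  } else {
    list(cohort)
  }
  rows <- lapply(names(groups) %||% "", function(g) {
    df <- groups[[if (g == "") 1L else g]]
    mo <- format(df$fit_date, "%Y-%m")
    tab <- tapply(df$fit_value >= fit_threshold, mo, function(z) {
      c(n = length(z), k = sum(z))
    })
    out <- data.frame(month = names(tab),
                      n_tests = vapply(tab, `[[`, numeric(1), "n"),
                      n_positive = vapply(tab, `[[`, numeric(1), "k"))
    if (by_device) out <- cbind(device = g, out)
    out$suppressed <- out$n_positive < min_positives
    ci <- t(mapply(function(k, n) wilson_ci(k, n, level),
                   out$n_positive, out$n_tests))
    out$positivity <- ifelse(out$suppressed, NA_real_,
                             out$n_positive / out$n_tests)
    out$lower <- ifelse(out$suppressed, NA_real_, ci[, 1])
    out$upper <- ifelse(out$suppressed, NA_real_, ci[, 2])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$month), , drop = FALSE]
}

#' Regression of monthly positivity on monthly testing volume
#'
#' Ordinary least squares of the monthly FIT-positivity proportion on the
#' monthly number of tests over a month range, using unsuppressed months
#' only. Quantifies whether months with more testing also see higher
#' positivity (a case-mix drift signature).
#'
#' @param series output of [monthly_trend()].
#' @param month_range optional `c(first, last)` month (`"YYYY-MM"`).
#' @return list with `r_squared`, `p_slope`, `slope`, `n_months`.
#' @export
volume_positivity_regression <- function(series, month_range = NULL) {
  df <- series[!series$suppressed, , drop = FALSE]
  if (!is.null(month_range)) {
    df <- df[df$month >= month_range[1] & df$month <= month_range[2], ,
             drop = FALSE]
  }
  if (nrow(df) < 3L) {
    fv_stop("volume_positivity_regression: fewer than 3 unsuppressed months in range",
            "fitvalid_insufficient_data_error")
  }
  fit <- stats::lm(positivity ~ n_tests, data = df)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_slope = sm$coefficients["n_tests", "Pr(>|t|)"],
       slope = sm$coefficients["n_tests", "Estimate"],
       n_months = nrow(df))
}

#' Cohort summary counts
#'
#' @param cohort prepared cohort with `crc` and `fit_value`.
#' @param fit_threshold positivity threshold, default 10.
#' @return one-row `data.frame`: `n`, `n_cancers`, `prevalence_pct`,
#'   `n_fit_positive`, `positivity_pct`.
#' @export
cohort_summary <- function(cohort, fit_threshold = 10) {
  check_columns(cohort, c("crc", "fit_value"), "cohort_summary")
  n <- nrow(cohort)
  data.frame(n = n, n_cancers = sum(cohort$crc),
             prevalence_pct = 100 * mean(cohort$crc),
             n_fit_positive = sum(cohort$fit_value >= fit_threshold),
             positivity_pct = 100 * mean(cohort$fit_value >= fit_threshold))
}

# Score-set for one cohort subset given a risk vector aligned with rows.
subset_scores <- function(cohort, risk, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cohort))
  risk_scores(risk = risk[rows], fit = cohort$fit_value[rows],
              y = cohort$crc[rows])
}

#' Assemble the full validation report
#'
#' Runs the complete battery per period and on all data: period summary
#' counts, matched-sensitivity threshold comparisons in local-current,
#' local-previous (prospective) and external modes, calibration summaries
#' for the raw model and (optionally) recalibrated variants plus the
#' FIT-spline comparator, and discrimination metrics (average precision and
#' c-statistic) for the model and the FIT test. Bootstrap intervals are
#' attached to the headline reduction when `B > 0`.
#'
#' @param cohort prepared cohort (columns `fit_value`, `crc`, `period`).
#' @param risk vector of model risk probabilities aligned with `cohort`.
#' @param external_threshold_pct optional externally derived percent
#'   threshold to evaluate (e.g. 0.64).
#' @param fit_threshold comparator FIT threshold, default 10.
#' @param B bootstrap replicates for the headline reduction (0 = none).
#' @param seed seed for bootstrap resampling.
#' @param quantile_ref optional [reference_fit_distribution()]; when given,
#'   a quantile-recalibrated model variant is included in the calibration
#'   table (the model is re-scored through `rescore`).
#' @param rescore function `(cohort, fit_values) -> risk` used to re-score
#'   patients with transformed FIT values; required for `quantile_ref`.
#' @return list of data frames: `periods`, `thresholds`, `calibration`,
#'   `discrimination`, plus `meta` (seed and settings).
#' @export
build_report <- function(cohort, risk, external_threshold_pct = NULL,
                         fit_threshold = 10, B = 0, seed = 1,
                         quantile_ref = NULL, rescore = NULL) {
  check_columns(cohort, c("fit_value", "crc", "period"), "build_report")
  if (!is.null(quantile_ref) && is.null(rescore)) {
    fv_stop("build_report: quantile_ref requires a rescore function",
            "fitvalid_parameter_error")
  }
  period_labels <- unique(cohort$period[cohort$period != "unassigned"])
  sets <- c(list(`All data` = seq_len(nrow(cohort))),
            stats::setNames(lapply(period_labels,
                                   function(p) which(cohort$period == p)),
                            period_labels))

  periods <- do.call(rbind, lapply(names(sets), function(nm) {
    cbind(period = nm, cohort_summary(cohort[sets[[nm]], , drop = FALSE],
                                      fit_threshold))
  }))

  thr_rows <- list()
  cal_rows <- list()
  dis_rows <- list()
  for (nm in names(sets)) {
    sc <- subset_scores(cohort, risk, sets[[nm]])
    thr <- matched_sensitivity_threshold(sc, fit_threshold)
    cmp <- referral_reduction(sc, as.numeric(thr), fit_threshold)
    row <- cbind(data.frame(period = nm, mode = "local current"), cmp)
    if (B > 0) {
      bs <- bootstrap_ci(function(d) {
        t <- matched_sensitivity_threshold(d, fit_threshold)
        referral_reduction(d, as.numeric(t), fit_threshold)$pct_reduction
      }, sc, B = B, seed = seed)
      row$pct_reduction_lower <- bs$lower
      row$pct_reduction_upper <- bs$upper
      row$significant <- bs$significant_reduction
    }
    thr_rows[[length(thr_rows) + 1L]] <- row
    if (!is.null(external_threshold_pct)) {
      ext <- external_threshold_evaluation(sc, external_threshold_pct,
                                           fit_threshold)
      thr_rows[[length(thr_rows) + 1L]] <-
        cbind(data.frame(period = nm, mode = "external"), ext)
    }

    cal_rows[[length(cal_rows) + 1L]] <-
      cbind(data.frame(period = nm, model = "risk-model"),
            calibration_summary(sc$y, sc$risk))
    spl <- fit_spline_model(sc$fit, sc$y)
    cal_rows[[length(cal_rows) + 1L]] <-
      cbind(data.frame(period = nm, model = "FIT-spline"),
            calibration_summary(sc$y, predict(spl, sc$fit)))
    if (!is.null(quantile_ref)) {
      fitq <- recalibrate_fit_quantile(sc$fit, quantile_ref)
      riskq <- rescore(cohort[sets[[nm]], , drop = FALSE], fitq)
      cal_rows[[length(cal_rows) + 1L]] <-
        cbind(data.frame(period = nm, model = "risk-model-quant"),
              calibration_summary(sc$y, riskq))
    }

    dis_rows[[length(dis_rows) + 1L]] <- data.frame(
      period = nm, model = "risk-model",
      average_precision = average_precision(sc),
      c_statistic = roc_and_cstat(sc)$c_statistic)
    fit_as_score <- data.frame(risk = clip_prob(sc$fit / 401 + 1e-6),
                               y = sc$y)
    dis_rows[[length(dis_rows) + 1L]] <- data.frame(
      period = nm, model = "FIT test",
      average_precision = average_precision(fit_as_score),
      c_statistic = roc_and_cstat(fit_as_score)$c_statistic)
  }

  # local-previous (prospective) rows over chronological periods
  if (length(period_labels) >= 2L) {
    per_scores <- lapply(period_labels, function(p) {
      subset_scores(cohort, risk, which(cohort$period == p))
    })
    names(per_scores) <- period_labels
    prosp <- prospective_simulation(per_scores, fit_threshold)
    if (!is.null(prosp) && nrow(prosp) > 0) {
      prosp_rows <- cbind(data.frame(period = prosp$period,
                                     mode = "local previous"),
                          prosp[, !(names(prosp) %in%
                                      c("period", "threshold_period")),
                                drop = FALSE])
      thr_rows[[length(thr_rows) + 1L]] <- prosp_rows
    }
  }

  fill_rbind <- function(rows) {
    cols <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) {
      for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
      r[, cols, drop = FALSE]
    }))
  }
  list(periods = periods,
       thresholds = fill_rbind(thr_rows),
       calibration = fill_rbind(cal_rows),
       discrimination = do.call(rbind, dis_rows),
       meta = list(seed = seed, B = B, fit_threshold = fit_threshold,
                   external_threshold_pct = external_threshold_pct,
                   generated = "deterministic given seed"))
}

#' Write a report bundle to CSV files
#'
#' @param report output of [build_report()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("periods", "thresholds", "calibration", "discrimination")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
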