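# Synthetic cohort generator.
#
# Emulates the statistical structure of a GP-requested FIT testing cohort:
# a zero-inflated, heavy-tailed FIT distribution censored to [0, 400] ug/g,
# low-prevalence cancer outcomes linked to predictors through a known
# logistic surrogate model, and temporal case-mix drift implemented by
# moving the FIT mixture (and, where needed, the age distribution) across
# calendar periods while the outcome model stays fixed.

# --- calendar helpers -------------------------------------------------------

month_start <- function(m) as.Date(paste0(m, "-01"))

month_seq <- function(start_month, end_month) {
  s <- month_start(start_month)
  e <- month_start(end_month)
  if (e < s) fv_stop("end_month must not precede start_month",
                     "fitvalid_parameter_error")
  format(seq(s, e, by = "month"), "%Y-%m")
}

days_in_month <- function(m) {
  s <- month_start(m)
  as.integer(seq(s, by = "month", length.out = 2)[2] - s)
}

# --- parameter container ----------------------------------------------------

#' Parameters for the synthetic cohort generator
#'
#' The defaults describe the marginal structure of a symptomatic
#' primary-care FIT population: 77% of reported FIT values below the
#' detection limit, a lognormal tail whose location/spread are fixed so that
#' 12% of all values are >= 10 ug/g and 4.2% are >= 100 ug/g, age roughly
#' normal (mean 62.7, SD 19.1, truncated to 18-103 years), 41.4% male,
#' lognormal platelets (median 267, quartiles ~224-318) and normal MCV
#' (mean 91.5 fL, SD 5.2). Predictors are drawn independently of one another;
#' their association with cancer arises solely through the surrogate model.
#'
#' @param n_patients total cohort size. May be omitted when `period_targets`
#'   carries per-period counts.
#' @param start_month,end_month generation window, `"YYYY-MM"` strings.
#' @param period_targets optional `data.frame` with columns `label`,
#'   `start_month`, `end_month`, and optionally `n`, `positivity`
#'   (target share of FIT >= 10 ug/g) and `prevalence` (target cancer
#'   fraction). Periods must tile the window without overlap.
#' @param fit_zero_mass probability that a reported FIT is below the
#'   detection limit (reported as 0).
#' @param fit_tail_log_mean,fit_tail_log_sd log-scale location and spread of
#'   the nonzero FIT component (lognormal, censored at 400 ug/g).
#' @param sex_male_frac probability of male sex.
#' @param age_dist named vector `mean`, `sd`, `min`, `max` (years).
#' @param plt_dist named vector `meanlog`, `sdlog` (platelets, 10^9/L).
#' @param mcv_dist named vector `mean`, `sd` (fL).
#' @param model the generating [surrogate_model()].
#' @param seed integer seed; mandatory, the generator keeps no global state.
#' @param frac_non_gp,frac_under18,frac_prior_crc,frac_short_followup,frac_missing_bloods
#'   optional contamination fractions used to exercise the
#'   inclusion/exclusion accounting; all default to 0 (a clean cohort).
#' @return an object of class `synthetic_params`.
#' @seealso [generate_cohort()], [scenario_sixperiod()]
#' @export
synthetic_params <- function(n_patients = NULL,
                             start_month = "2017-01",
                             end_month = "2023-06",
                             period_targets = NULL,
                             fit_zero_mass = 0.77,
                             fit_tail_log_mean = 2.4329,
                             fit_tail_log_sd = 2.3904,
                             sex_male_frac = 0.414,
                             age_dist = c(mean = 62.7, sd = 19.1,
                                          min = 18, max = 103),
                             plt_dist = c(meanlog = log(267), sdlog = 0.257),
                             mcv_dist = c(mean = 91.5, sd = 5.2),
                             model = default_surrogate_model(),
                             seed,
                             frac_non_gp = 0,
                             frac_under18 = 0,
                             frac_prior_crc = 0,
                             frac_short_followup = 0,
                             frac_missing_bloods = 0) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    fv_stop("synthetic_params: field 'seed' is mandatory and must be a single integer",
            "fitvalid_parameter_error")
  }
  fracs <- c(fit_zero_mass = fit_zero_mass, sex_male_frac = sex_male_frac,
             frac_non_gp = frac_non_gp, frac_under18 = frac_under18,
             frac_prior_crc = frac_prior_crc,
             frac_short_followup = frac_short_followup,
             frac_missing_bloods = frac_missing_bloods)
  for (nm in names(fracs)) {
    if (!is.finite(fracs[[nm]]) || fracs[[nm]] < 0 || fracs[[nm]] > 1) {
      fv_stop(sprintf("synthetic_params: field '%s' must lie in [0, 1]", nm),
              "fitvalid_parameter_error")
    }
  }
  if (fit_tail_log_sd <= 0) {
    fv_stop("synthetic_params: field 'fit_tail_log_sd' must be positive",
            "fitvalid_parameter_error")
  }
  months <- month_seq(start_month, end_month)

  if (is.null(period_targets)) {
    period_targets <- data.frame(label = "all", start_month = start_month,
                                 end_month = end_month,
                                 n = NA_real_, positivity = NA_real_,
                                 prevalence = NA_real_)
  }
  period_targets <- as.data.frame(period_targets)
  check_columns(period_targets, c("label", "start_month", "end_month"),
                "synthetic_params")
  for (opt in c("n", "positivity", "prevalence")) {
    if (is.null(period_targets[[opt]])) period_targets[[opt]] <- NA_real_
  }
  covered <- unlist(lapply(seq_len(nrow(period_targets)), function(i) {
    month_seq(period_targets$start_month[i], period_targets$end_month[i])
  }))
  if (anyDuplicated(covered)) {
    fv_stop("synthetic_params: field 'period_targets' has overlapping periods",
            "fitvalid_parameter_error")
  }
  if (!all(covered %in% months)) {
    fv_stop("synthetic_params: field 'period_targets' extends outside [start_month, end_month]",
            "fitvalid_parameter_error")
  }
  pos <- period_targets$positivity
  prev <- period_targets$prevalence
  if (any(!is.na(pos) & (pos < 0 | pos > 1)) ||
      any(!is.na(prev) & (prev < 0 | prev > 1))) {
    fv_stop("synthetic_params: field 'period_targets' fractions must lie in [0, 1]",
            "fitvalid_parameter_error")
  }

  # resolve per-period counts
  if (all(is.na(period_targets$n))) {
    if (is.null(n_patients)) {
      fv_stop("synthetic_params: field 'n_patients' is required when period_targets has no counts",
              "fitvalid_parameter_error")
    }
    len <- vapply(seq_len(nrow(period_targets)), function(i) {
      length(month_seq(period_targets$start_month[i],
                       period_targets$end_month[i]))
    }, integer(1))
    alloc <- floor(n_patients * len / sum(len))
    rem <- n_patients - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    period_targets$n <- alloc
  } else if (!is.null(n_patients) &&
             abs(sum(period_targets$n) - n_patients) > 0.5) {
    alloc <- floor(n_patients * period_targets$n / sum(period_targets$n))
    rem <- n_patients - sum(alloc)
    ord <- order(period_targets$n, decreasing = TRUE)
    if (rem > 0) alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
    period_targets$n <- alloc
  }
  if (is.null(n_patients)) n_patients <- sum(period_targets$n)
  if (n_patients <= 0) {
    fv_stop("synthetic_params: field 'n_patients' must be positive",
            "fitvalid_parameter_error")
  }

  structure(list(n_patients = as.integer(n_patients),
                 start_month = start_month, end_month = end_month,
                 period_targets = period_targets,
                 fit_zero_mass = fit_zero_mass,
                 fit_tail_log_mean = fit_tail_log_mean,
                 fit_tail_log_sd = fit_tail_log_sd,
                 sex_male_frac = sex_male_frac,
                 age_dist = age_dist, plt_dist = plt_dist,
                 mcv_dist = mcv_dist, model = model,
                 seed = as.integer(seed),
                 frac_non_gp = frac_non_gp, frac_under18 = frac_under18,
                 frac_prior_crc = frac_prior_crc,
                 frac_short_followup = frac_short_followup,
                 frac_missing_bloods = frac_missing_bloods),
            class = "synthetic_params")
}

#' Six-period drifting case-mix scenario
#'
#' Returns generator parameters for the six analysis periods of a
#' seven-year GP FIT testing window, with per-period patient counts, cancer
#' prevalence and FIT-positivity targets that reproduce the documented drift
#' from 8.8% to 16.7% positivity. The generator meets each period's joint
#' (positivity, prevalence) target by moving the FIT mixture, with an age
#' shift as a secondary dial, while the outcome model stays fixed.
#'
#' @param n_patients optional total size; per-period counts are scaled
#'   proportionally. Default keeps the printed per-period counts
#'   (48,523 patients in total).
#' @param seed integer seed passed through to [synthetic_params()].
#' @param ... further arguments forwarded to [synthetic_params()].
#' @return a `synthetic_params` object.
#' @examples
#' p <- scenario_sixperiod(seed = 1)
#' p$period_targets
#' @export
scenario_sixperiod <- function(n_patients = NULL, seed = 1, ...) {
  targets <- data.frame(
    label = c("Pre-COVID", "COVID", "Post-COVID",
              "2022 H1", "2022 H2", "2023 H1"),
    start_month = c("2017-01", "2020-03", "2021-05",
                    "2022-01", "2022-07", "2023-01"),
    end_month = c("2020-02", "2021-04", "2021-12",
                  "2022-06", "2022-12", "2023-06"),
    n = c(10379, 8890, 7472, 5972, 7490, 8320),
    positivity = c(0.088, 0.096, 0.102, 0.125, 0.144, 0.167),
    prevalence = c(0.0119, 0.0144, 0.0132, 0.0147, 0.0139, 0.0109),
    stringsAsFactors = FALSE)
  synthetic_params(n_patients = n_patients, start_month = "2017-01",
                   end_month = "2023-06", period_targets = targets,
                   seed = seed, ...)
}

# --- period calibration -----------------------------------------------------

# Tail survivor function above `x` for the lognormal FIT component.
tail_surv <- function(x, meanlog, sdlog) {
  stats::pnorm((log(x) - meanlog) / sdlog, lower.tail = FALSE)
}

# Deterministic profile sample + tail quadrature used to evaluate the
# expected prevalence implied by a candidate FIT mixture. Quadrature, not
# simulation: expected risks are averaged, so no Bernoulli noise enters.
calibration_profiles <- function(params, m = 4000L) {
  with_seed(986532L, {
    list(u_age = stats::runif(m),
         male = stats::rbinom(m, 1L, params$sex_male_frac),
         plt = stats::rlnorm(m, params$plt_dist[["meanlog"]],
                             params$plt_dist[["sdlog"]]),
         mcv = stats::rnorm(m, params$mcv_dist[["mean"]],
                            params$mcv_dist[["sd"]]))
  })
}

# Truncated-normal age via inverse CDF, supporting a location shift.
age_from_u <- function(u, age_dist, shift = 0) {
  m <- age_dist[["mean"]] + shift
  s <- age_dist[["sd"]]
  lo <- stats::pnorm(age_dist[["min"]], m, s)
  hi <- stats::pnorm(age_dist[["max"]], m, s)
  stats::qnorm(lo + u * (hi - lo), m, s)
}

expected_prevalence <- function(meanlog, zero_mass, age_shift,
                                params, prof, qgrid) {
  b <- params$model$coefficients
  age <- age_from_u(prof$u_age, params$age_dist, age_shift)
  lp_other <- b[["age"]] * age + b[["male"]] * prof$male +
    b[["plt"]] * prof$plt + b[["mcv"]] * prof$mcv
  ft <- pmin(exp(meanlog + params$fit_tail_log_sd * qgrid), 400)
  rep_fit <- ifelse(ft < 1.3, 0, ft)       # below-LOD tail draws report as 0
  p_tail <- mean(stats::plogis(outer(b[["intercept"]] + lp_other,
                                     b[["log_fit"]] * log(rep_fit + 1), "+")))
  p_zero <- mean(stats::plogis(b[["intercept"]] + lp_other))
  zero_mass * p_zero + (1 - zero_mass) * p_tail
}

# Solve the per-period mixture so that the share of reported FIT >= 10
# matches the positivity target and (when given) the expected outcome rate
# under the fixed surrogate model matches the prevalence target. Zero mass
# follows analytically from positivity once the tail location is fixed; the
# tail location is searched within the band keeping the zero mass plausible
# (0.50-0.97), and an age-location shift takes over when the prevalence
# target is outside the reachable range.
.calibration_cache <- new.env(parent = emptyenv())

calibrate_periods <- function(params) {
  pt <- params$period_targets
  sdlog <- params$fit_tail_log_sd
  # memoise: the solve depends only on targets, mixture shape and model
  key <- paste(c(pt$positivity, pt$prevalence, params$fit_tail_log_mean,
                 sdlog, params$fit_zero_mass, params$sex_male_frac,
                 params$age_dist, params$plt_dist, params$mcv_dist,
                 params$model$coefficients), collapse = "|")
  cached <- .calibration_cache[[key]]
  if (!is.null(cached) && identical(cached$labels, pt$label)) {
    return(cached$mix)
  }
  out <- data.frame(label = pt$label,
                    meanlog = params$fit_tail_log_mean,
                    zero_mass = params$fit_zero_mass,
                    age_shift = 0)
  need <- !is.na(pt$positivity)
  if (!any(need)) {
    .calibration_cache[[key]] <- list(labels = pt$label, mix = out)
    return(out)
  }
  prof <- calibration_profiles(params)
  qgrid <- stats::qnorm((seq_len(200) - 0.5) / 200)

  mu_for_z <- function(z, pos) {
    s10 <- min(pos / (1 - z), 0.999)
    log(10) - sdlog * stats::qnorm(1 - s10)
  }
  for (i in which(need)) {
    pos <- pt$positivity[i]
    if (pos == 0) { out$zero_mass[i] <- 1; next }
    if (is.na(pt$prevalence[i])) {
      s10 <- tail_surv(10, out$meanlog[i], sdlog)
      out$zero_mass[i] <- max(0, 1 - pos / s10)
      next
    }
    prev <- pt$prevalence[i]
    mu_lo <- mu_for_z(0.50, pos)
    mu_hi <- mu_for_z(0.97, pos)
    zp <- function(mu) 1 - pos / tail_surv(10, mu, sdlog)
    f <- function(mu) expected_prevalence(mu, zp(mu), 0, params, prof,
                                          qgrid) - prev
    flo <- f(mu_lo); fhi <- f(mu_hi)
    if (flo > 0) {
      # prevalence target below reach of the FIT mixture: younger case-mix
      mu <- mu_lo
      g <- function(d) expected_prevalence(mu, zp(mu), d, params, prof,
                                           qgrid) - prev
      out$age_shift[i] <- stats::uniroot(g, c(-25, 0), tol = 1e-4)$root
    } else if (fhi < 0) {
      mu <- mu_hi
      g <- function(d) expected_prevalence(mu, zp(mu), d, params, prof,
                                           qgrid) - prev
      out$age_shift[i] <- stats::uniroot(g, c(0, 25), tol = 1e-4)$root
    } else {
      mu <- stats::uniroot(f, c(mu_lo, mu_hi), tol = 1e-4)$root
    }
    out$meanlog[i] <- mu
    out$zero_mass[i] <- zp(mu)
  }
  .calibration_cache[[key]] <- list(labels = pt$label, mix = out)
  out
}

# --- cohort generation ------------------------------------------------------

#' Generate a synthetic patient-level FIT cohort
#'
#' Draws one record per patient: a FIT date uniform within its calendar
#' month, a raw FIT value from the zero/lognormal mixture (reported value
#' censored to `[0, 400]` with sub-detection values reported as 0), the four
#' other predictors from their marginal distributions, and a cancer outcome
#' drawn from the surrogate-model probability of the generated record.
#' Cancer dates fall 0-179 days after the FIT, follow-up ends 400 days
#' after, and a buffer-device flag switches on from July 2021. Output is
#' deterministic given `params$seed`.
#'
#' @param params a [synthetic_params()] object.
#' @return a `data.frame` in the standard cohort layout: `patient_id`,
#'   `fit_date`, `fit_value`, `age`, `sex`, `plt`, `mcv`, `crc`, `crc_date`,
#'   `followup_end`, `gp_requested`, `device`, `period`. The calibrated
#'   per-period mixture is attached as attribute `"mixture"`.
#' @examples
#' coh <- generate_cohort(synthetic_params(n_patients = 500, seed = 42))
#' mean(coh$fit_value >= 10)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  mix <- calibrate_periods(params)
  pt <- params$period_targets

  chunks <- with_seed(params$seed, {
    lapply(seq_len(nrow(pt)), function(i) {
      n <- pt$n[i]
      if (n == 0) return(NULL)
      months <- month_seq(pt$start_month[i], pt$end_month[i])
      mo <- months[sample.int(length(months), n, replace = TRUE)]
      day <- floor(stats::runif(n) * vapply(mo, days_in_month, integer(1))) + 1
      fit_date <- as.Date(paste0(mo, "-", sprintf("%02d", day)))

      age <- age_from_u(stats::runif(n), params$age_dist, mix$age_shift[i])
      sex <- ifelse(stats::runif(n) < params$sex_male_frac, "male", "female")
      plt <- stats::rlnorm(n, params$plt_dist[["meanlog"]],
                           params$plt_dist[["sdlog"]])
      mcv <- stats::rnorm(n, params$mcv_dist[["mean"]],
                          params$mcv_dist[["sd"]])

      below_lod <- stats::runif(n) < mix$zero_mass[i]
      fit_raw <- ifelse(below_lod,
                        stats::runif(n, 0, 1.3),
                        stats::rlnorm(n, mix$meanlog[i],
                                      params$fit_tail_log_sd))
      fit_value <- censor_fit(fit_raw)

      p <- true_risk(params$model,
                     data.frame(fit_value = fit_value, age = age, sex = sex,
                                plt = plt, mcv = mcv))
      crc <- as.integer(stats::runif(n) < p)
      crc_date <- as.Date(rep(NA, n))
      crc_date[crc == 1] <- fit_date[crc == 1] +
        floor(stats::runif(sum(crc), 0, 180))
      followup_end <- fit_date + 400L
      gp_requested <- rep(1L, n)
      device <- as.integer(fit_date >= as.Date("2021-07-01"))

      # optional contamination used to exercise exclusion accounting
      if (params$frac_non_gp > 0) {
        gp_requested[stats::runif(n) < params$frac_non_gp] <- 0L
      }
      if (params$frac_under18 > 0) {
        k <- stats::runif(n) < params$frac_under18
        age[k] <- stats::runif(sum(k), 16, 17.9)
      }
      if (params$frac_short_followup > 0) {
        k <- stats::runif(n) < params$frac_short_followup
        followup_end[k] <- fit_date[k] + floor(stats::runif(sum(k), 0, 180))
      }
      if (params$frac_prior_crc > 0) {
        k <- stats::runif(n) < params$frac_prior_crc
        crc[k] <- 1L
        crc_date[k] <- fit_date[k] - floor(stats::runif(sum(k), 10, 400))
      }
      if (params$frac_missing_bloods > 0) {
        k <- stats::runif(n) < params$frac_missing_bloods
        plt[k] <- NA_real_
        mcv[stats::runif(n) < params$frac_missing_bloods / 2] <- NA_real_
      }

      data.frame(fit_date = fit_date, fit_value = fit_value, age = age,
                 sex = sex, plt = plt, mcv = mcv, crc = crc,
                 crc_date = crc_date, followup_end = followup_end,
                 gp_requested = gp_requested, device = device,
                 period = pt$label[i], stringsAsFactors = FALSE)
    })
  })
  cohort <- do.call(rbind, chunks)
  rownames(cohort) <- NULL
  cohort <- cbind(patient_id = sprintf("P%06d", seq_len(nrow(cohort))),
                  cohort, stringsAsFactors = FALSE)
  attr(cohort, "mixture") <- mix
  cohort
}

#' Read / write the standard cohort CSV
#'
#' Dates travel as ISO-8601 strings; internally they are `Date` objects.
#'
#' @param path file path.
#' @param cohort a cohort `data.frame`.
#' @return `read_cohort` returns the cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("fit_date", "crc_date", "followup_end"), names(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
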