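# Cohort preparation: FIT value handling, predictor-window selection,
# outcome definition, inclusion/exclusion accounting and period assignment.

#' Censor a raw FIT value to the reporting range
#'
#' Values below the analyser's limit of detection (1.3 ug/g) are reported as
#' zero and values above the limit of linearity (400 ug/g) as 400. The
#' operation is idempotent.
#'
#' @param fit_raw non-negative raw FIT value(s), ug Hb/g.
#' @param lod limit of detection; default 1.3.
#' @param lol limit of linearity; default 400.
#' @return reported FIT value(s) in `[0, lol]`.
#' @examples
#' censor_fit(c(1.2, 10, 5000))  # 0, 10, 400
#' @export
censor_fit <- function(fit_raw, lod = 1.3, lol = 400) {
  if (any(fit_raw < 0, na.rm = TRUE)) {
    fv_stop("censor_fit: raw FIT values must be non-negative",
            "fitvalid_domain_error")
  }
  out <- ifelse(fit_raw < lod, 0, pmin(fit_raw, lol))
  out
}

#' Floor reported FIT values for model input
#'
#' Reported values below 4 ug/g are replaced with 4 before entering an
#' externally derived risk equation whose derivation data had 4 ug/g as its
#' minimum. The floor applies only to model input, never to FIT-positivity
#' classification.
#'
#' @param fit_reported reported FIT value(s) in `[0, 400]`.
#' @param floor the floor, default 4.
#' @return floored value(s).
#' @export
floor_fit_for_model <- function(fit_reported, floor = 4) {
  pmax(fit_reported, floor)
}

#' Select the blood-test record closest to the FIT date
#'
#' Among measurements dated within a closed window around the FIT date
#' (default -365 to +14 days) and not after the cancer date, returns the
#' value whose date is closest to the FIT. Equidistant pre- and post-FIT
#' records resolve to the earlier (pre-test) record, which cannot have been
#' influenced by post-test workup. Absence of a qualifying record is a value
#' (`NA`), not an error.
#'
#' @param dates measurement dates (`Date`).
#' @param values measurement values.
#' @param fit_date the FIT date (`Date`).
#' @param crc_date cancer date (`Date`) or `NA`; measurements after it are
#'   excluded.
#' @param window integer vector `c(lower, upper)` in days relative to the
#'   FIT date, endpoints inclusive.
#' @return the selected value, or `NA` if none qualifies.
#' @examples
#' d <- as.Date("2020-06-01") + c(-400, -10)
#' select_predictor_record(d, c(100, 200), as.Date("2020-06-01"))  # 200
#' @export
select_predictor_record <- function(dates, values, fit_date, crc_date = NA,
                                    window = c(-365, 14)) {
  stopifnot(length(dates) == length(values))
  if (length(dates) == 0L) return(NA)
  delta <- as.numeric(dates - fit_date)
  ok <- delta >= window[1] & delta <= window[2]
  if (!is.na(crc_date)) ok <- ok & dates <= crc_date
  if (!any(ok)) return(NA)
  cand <- which(ok)
  d <- abs(delta[cand])
  best <- d == min(d)
  if (sum(best) > 1L) {
    # tie: prefer the earlier (pre-test) record
    sel <- cand[best][which.min(delta[cand][best])]
  } else {
    sel <- cand[which.min(d)]
  }
  values[sel]
}

#' Define the cancer outcome within a follow-up window
#'
#' A patient is an outcome case when a cancer date exists within
#' `[0, followup_days]` days after the FIT date. Cancers recorded after the
#' window count as non-cancers, keeping the case definition comparable
#' across time periods. A cancer date before the FIT date is not an outcome
#' of the test: those records are returned as `NA` with a warning and are
#' expected to be removed by [apply_inclusion()] as prior cancers.
#'
#' @param crc_date cancer date(s) (`Date`, `NA` when none).
#' @param fit_date FIT date(s) (`Date`).
#' @param followup_days follow-up window length; 180 by default, 365 for the
#'   sensitivity analysis.
#' @return integer vector of 0/1 outcomes (`NA` for prior cancers).
#' @examples
#' f <- as.Date("2020-01-01")
#' define_outcome(f + 200, f, followup_days = 180)  # 0
#' define_outcome(f + 200, f, followup_days = 365)  # 1
#' @export
define_outcome <- function(crc_date, fit_date, followup_days = 180) {
  if (any(is.na(fit_date))) {
    fv_stop("define_outcome: fit_date must be present", "fitvalid_domain_error")
  }
  delta <- as.numeric(crc_date - fit_date)
  out <- ifelse(is.na(delta), 0L,
                ifelse(delta < 0, NA_integer_,
                       as.integer(delta <= followup_days)))
  if (anyNA(out)) {
    warning("define_outcome: cancer date(s) before FIT date; records flagged NA for prior-cancer exclusion")
  }
  out
}

#' Apply inclusion and exclusion criteria
#'
#' Removes, in order: FITs not requested by a GP; patients under 18;
#' insufficient follow-up after the FIT (shorter than `followup_days`,
#' including cancer patients, whose inclusion would otherwise bias
#' prevalence because non-cancer patients are always excluded on this
#' criterion); cancer recorded before the first FIT; and missing platelet
#' or MCV results (complete-case analysis). The tally is order-dependent:
#' each record counts against the first criterion that removes it.
#'
#' @param cohort a cohort `data.frame` with columns `fit_date`, `age`,
#'   `plt`, `mcv`, `crc`, `crc_date`, `followup_end`, `gp_requested`.
#' @param followup_days required follow-up, default 180.
#' @return a list with elements `cohort` (surviving rows, values untouched)
#'   and `tally` (named integer vector of removals per criterion, class
#'   `exclusion_tally`).
#' @export
apply_inclusion <- function(cohort, followup_days = 180) {
  check_columns(cohort,
                c("fit_date", "age", "plt", "mcv", "crc", "crc_date",
                  "followup_end", "gp_requested"),
                "apply_inclusion")
  n_in <- nrow(cohort)
  tally <- c(non_gp = 0L, under_18 = 0L, insufficient_followup = 0L,
             prior_crc = 0L, missing_bloods = 0L)
  drop1 <- cohort$gp_requested == 0
  tally["non_gp"] <- sum(drop1)
  cohort <- cohort[!drop1, , drop = FALSE]

  drop2 <- cohort$age < 18
  tally["under_18"] <- sum(drop2)
  cohort <- cohort[!drop2, , drop = FALSE]

  drop3 <- as.numeric(cohort$followup_end - cohort$fit_date) < followup_days
  tally["insufficient_followup"] <- sum(drop3)
  cohort <- cohort[!drop3, , drop = FALSE]

  drop4 <- !is.na(cohort$crc_date) & cohort$crc_date < cohort$fit_date
  tally["prior_crc"] <- sum(drop4)
  cohort <- cohort[!drop4, , drop = FALSE]

  drop5 <- is.na(cohort$plt) | is.na(cohort$mcv)
  tally["missing_bloods"] <- sum(drop5)
  cohort <- cohort[!drop5, , drop = FALSE]

  rownames(cohort) <- NULL
  stopifnot(sum(tally) == n_in - nrow(cohort))
  class(tally) <- c("exclusion_tally", class(tally))
  attr(tally, "n_input") <- n_in
  attr(tally, "n_output") <- nrow(cohort)
  list(cohort = cohort, tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat(sprintf("Exclusions (%d -> %d records):\n",
              attr(x, "n_input"), attr(x, "n_output")))
  for (nm in names(x)) cat(sprintf("  %-22s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Default six-period specification
#'
#' Month ranges of the six analysis periods: a pre-pandemic period, the
#' COVID period, and four post-COVID half-year-scale periods. July and
#' August 2023 fall in no period so the last three periods keep equal
#' duration and seasonality; dates outside every period are labelled
#' `"unassigned"` by [assign_periods()].
#'
#' @return `data.frame` with columns `label`, `start_month`, `end_month`.
#' @export
period_spec_default <- function() {
  data.frame(
    label = c("Pre-COVID", "COVID", "Post-COVID",
              "2022 H1", "2022 H2", "2023 H1"),
    start_month = c("2017-01", "2020-03", "2021-05",
                    "2022-01", "2022-07", "2023-01"),
    end_month = c("2020-02", "2021-04", "2021-12",
                  "2022-06", "2022-12", "2023-06"),
    stringsAsFactors = FALSE)
}

#' Assign calendar periods to FIT dates
#'
#' Labels each date by the period whose month range contains it. Dates in no
#' period are labelled `"unassigned"`: they are retained for whole-cohort
#' analyses and dropped from period-level analyses.
#'
#' @param fit_dates `Date` vector.
#' @param period_spec `data.frame` with `label`, `start_month`, `end_month`
#'   (non-overlapping); default [period_spec_default()].
#' @return character vector of labels.
#' @examples
#' assign_periods(as.Date("2020-03-15"))  # "COVID"
#' assign_periods(as.Date("2023-07-10"))  # "unassigned"
#' @export
assign_periods <- function(fit_dates, period_spec = period_spec_default()) {
  check_columns(period_spec, c("label", "start_month", "end_month"),
                "assign_periods")
  covered <- unlist(lapply(seq_len(nrow(period_spec)), function(i) {
    month_seq(period_spec$start_month[i], period_spec$end_month[i])
  }))
  if (anyDuplicated(covered)) {
    fv_stop("assign_periods: period_spec has overlapping periods",
            "fitvalid_config_error")
  }
  labels <- rep("unassigned", length(fit_dates))
  mo <- format(fit_dates, "%Y-%m")
  for (i in seq_len(nrow(period_spec))) {
    labels[mo %in% month_seq(period_spec$start_month[i],
                             period_spec$end_month[i])] <-
      period_spec$label[i]
  }
  labels
}

#' Prepare a raw cohort for validation
#'
#' Convenience wrapper running the preparation steps in order: censor FIT
#' values (when a raw column is supplied), apply inclusion/exclusion,
#' define the outcome within the follow-up window, and assign periods.
#'
#' @param cohort raw cohort `data.frame` (standard schema; `fit_value` holds
#'   reported values, or supply `fit_raw` to be censored first. When both
#'   are present the reported column wins and a warning is issued).
#' @param followup_days outcome follow-up window, default 180.
#' @param period_spec period specification or `NULL` to skip assignment.
#' @return list with `cohort` (prepared, outcome in column `crc`) and
#'   `tally` (exclusion accounting).
#' @export
prepare_cohort <- function(cohort, followup_days = 180,
                           period_spec = period_spec_default()) {
  if (!is.null(cohort$fit_raw)) {
    if (!is.null(cohort$fit_value)) {
      warning("prepare_cohort: both fit_raw and fit_value supplied; using fit_value")
    } else {
      cohort$fit_value <- censor_fit(cohort$fit_raw)
    }
  }
  check_columns(cohort, c("fit_value", "fit_date"), "prepare_cohort")
  res <- apply_inclusion(cohort, followup_days = followup_days)
  coh <- res$cohort
  coh$crc <- define_outcome(coh$crc_date, coh$fit_date,
                            followup_days = followup_days)
  if (!is.null(period_spec)) {
    coh$period <- assign_periods(coh$fit_date, period_spec)
  }
  list(cohort = coh, tally = res$tally)
}
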