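# Matched-sensitivity threshold selection and referral-reduction metrics:
# the core clinical comparison of a risk model against the FIT >= 10 ug/g
# referral rule.

#' FIT positivity at a threshold
#'
#' @param fit_reported reported FIT values, ug Hb/g.
#' @param fit_threshold referral threshold, default 10; the comparison is
#'   inclusive (`>=`), mirroring clinical convention.
#' @return integer 0/1 vector.
#' @export
fit_positive <- function(fit_reported, fit_threshold = 10) {
  as.integer(fit_reported >= fit_threshold)
}

# Cancer count and positive count of the rule risk >= t for every distinct
# observed risk value, sorted by decreasing threshold. Candidate thresholds
# are observed values only: any t between consecutive observed values yields
# identical classifications.
risk_sweep <- function(risk, y) {
  ord <- order(risk, decreasing = TRUE)
  r <- risk[ord]
  cum_tp <- cumsum(y[ord])
  n_pos <- seq_along(r)
  # keep the last index of each tied block: counts of the rule risk >= r
  idx <- which(!duplicated(r, fromLast = TRUE))
  data.frame(threshold = r[idx], tp = cum_tp[idx], n_pos = n_pos[idx])
}

#' Matched-sensitivity risk threshold
#'
#' Selects the model risk threshold that captures the same number of cancers
#' as the FIT test at `fit_threshold` (default 10 ug/g) with as few positive
#' tests as possible: the largest observed risk value whose cancer count
#' equals the FIT rule's cancer count. When tied risk scores make exact
#' equality unattainable, the largest threshold capturing *at least* that
#' many cancers is returned (never fewer cancers than FIT) and a message is
#' logged; set `relax = "exact"` to error instead.
#'
#' @param scores a [risk_scores()] data frame (`risk`, `fit`, `y`).
#' @param fit_threshold comparator FIT threshold, default 10.
#' @param relax `"at_least"` (default) or `"exact"` tie handling.
#' @return the selected threshold on the probability scale, with attributes
#'   `target_tp` (cancers detected by FIT), `tp` (cancers detected by the
#'   model at the threshold) and `relaxed` (logical).
#' @examples
#' s <- risk_scores(risk = c(.9, .8, .7, .6, .5, .4, .3, .2),
#'                  fit  = c(200, 15, 12, 3, 11, 2, 1, 0),
#'                  y    = c(1, 1, 0, 1, 0, 0, 0, 0))
#' matched_sensitivity_threshold(s)  # 0.8
#' @export
matched_sensitivity_threshold <- function(scores, fit_threshold = 10,
                                          relax = c("at_least", "exact")) {
  relax <- match.arg(relax)
  check_scores(scores, "matched_sensitivity_threshold")
  target_tp <- sum(scores$y == 1 & scores$fit >= fit_threshold)
  if (target_tp == 0L) {
    fv_stop("matched_sensitivity_threshold: FIT detects no cancers at this threshold; matched metric undefined",
            "fitvalid_degenerate_error")
  }
  sweep <- risk_sweep(scores$risk, scores$y)
  exact <- sweep$threshold[sweep$tp == target_tp]
  relaxed <- length(exact) == 0L
  if (!relaxed) {
    thr <- max(exact)
    tp <- target_tp
  } else {
    if (relax == "exact") {
      fv_stop("matched_sensitivity_threshold: tied risk scores prevent exact cancer-count match",
              "fitvalid_degenerate_error")
    }
    ok <- sweep$tp >= target_tp
    thr <- max(sweep$threshold[ok])
    tp <- sweep$tp[match(thr, sweep$threshold)]
    message(sprintf(
      "matched_sensitivity_threshold: exact match unattainable (score ties); using threshold capturing %d >= %d cancers",
      tp, target_tp))
  }
  structure(thr, target_tp = target_tp, tp = tp, relaxed = relaxed)
}

#' Referral-reduction comparison at a risk threshold
#'
#' Fills the full comparison between the rule `risk >= threshold` and the
#' rule `fit >= fit_threshold`: positive counts, percent change in positive
#' tests (negative values are reductions in referrals), positives per 1000
#' tests, sensitivities, their difference in percentage points, and the
#' absolute number of cancers missed (negative) or gained (positive)
#' relative to FIT.
#'
#' @param scores a [risk_scores()] data frame.
#' @param threshold model risk threshold on the probability scale (from any
#'   source: locally matched, a previous period, or external).
#' @param fit_threshold comparator FIT threshold, default 10.
#' @return one-row `data.frame` of class `threshold_comparison` with columns
#'   `threshold_pct`, `n_pos_model`, `n_pos_fit`, `pct_reduction`,
#'   `pos_per_1000_model`, `pos_per_1000_fit`, `sens_model`, `sens_fit`,
#'   `delta_sens`, `n_cancers_total`, `n_missed_or_gained`.
#' @export
referral_reduction <- function(scores, threshold, fit_threshold = 10) {
  check_scores(scores, "referral_reduction")
  n <- nrow(scores)
  pos_m <- scores$risk >= threshold
  pos_f <- scores$fit >= fit_threshold
  n_pos_fit <- sum(pos_f)
  if (n_pos_fit == 0L) {
    fv_stop("referral_reduction: no FIT-positive tests; percent reduction undefined",
            "fitvalid_degenerate_error")
  }
  n_pos_model <- sum(pos_m)
  ncase <- sum(scores$y == 1)
  tp_m <- sum(pos_m & scores$y == 1)
  tp_f <- sum(pos_f & scores$y == 1)
  out <- data.frame(
    threshold_pct = as.numeric(threshold) * 100,
    n_pos_model = n_pos_model,
    n_pos_fit = n_pos_fit,
    pct_reduction = (n_pos_model - n_pos_fit) / n_pos_fit * 100,
    pos_per_1000_model = n_pos_model / n * 1000,
    pos_per_1000_fit = n_pos_fit / n * 1000,
    sens_model = tp_m / ncase * 100,
    sens_fit = tp_f / ncase * 100,
    delta_sens = (tp_m - tp_f) / ncase * 100,
    n_cancers_total = ncase,
    n_missed_or_gained = tp_m - tp_f)
  class(out) <- c("threshold_comparison", class(out))
  attr(out, "sign_convention") <-
    "negative values indicate reductions in, positive values increases in referrals"
  out
}

#' Evaluate an externally supplied percent threshold
#'
#' Identical mechanics to [referral_reduction()] with the threshold given on
#' the percent scale, as referral thresholds are usually published (for
#' example 0.64%).
#'
#' @param scores a [risk_scores()] data frame.
#' @param threshold_pct risk threshold in percent, in (0, 100).
#' @param fit_threshold comparator FIT threshold, default 10.
#' @return a `threshold_comparison` row.
#' @export
external_threshold_evaluation <- function(scores, threshold_pct,
                                          fit_threshold = 10) {
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    fv_stop("external_threshold_evaluation: threshold_pct must lie in (0, 100)",
            "fitvalid_domain_error")
  }
  referral_reduction(scores, threshold_pct / 100,
                     fit_threshold = fit_threshold)
}

#' Prospective threshold simulation across periods
#'
#' Emulates real-world deployment: for each period after the first, the
#' matched-sensitivity threshold is selected on the *previous* period's data
#' and evaluated on the current period. A period in which FIT detects no
#' cancers cannot supply a threshold; that transition is skipped with a
#' warning.
#'
#' @param period_scores named list of [risk_scores()] data frames in
#'   chronological order (names are period labels).
#' @param fit_threshold comparator FIT threshold, default 10.
#' @return `data.frame` with one `threshold_comparison` row per evaluated
#'   period, plus columns `period` and `threshold_period` (where the
#'   threshold came from).
#' @export
prospective_simulation <- function(period_scores, fit_threshold = 10) {
  if (length(period_scores) < 2L) {
    fv_stop("prospective_simulation: at least two periods are required",
            "fitvalid_parameter_error")
  }
  labels <- names(period_scores) %||% as.character(seq_along(period_scores))
  rows <- list()
  for (k in seq_along(period_scores)[-1]) {
    thr <- tryCatch(
      matched_sensitivity_threshold(period_scores[[k - 1]],
                                    fit_threshold = fit_threshold),
      fitvalid_degenerate_error = function(e) {
        warning(sprintf(
          "prospective_simulation: period '%s' has no FIT-detected cancers; transition to '%s' skipped",
          labels[k - 1], labels[k]))
        NULL
      })
    if (is.null(thr)) next
    cmp <- referral_reduction(period_scores[[k]], as.numeric(thr),
                              fit_threshold = fit_threshold)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(period = labels[k],
                       threshold_period = labels[k - 1]), cmp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
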