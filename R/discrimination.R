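# ROC / precision-recall machinery with explicit interpolation conventions,
# and the test-reduction curve comparing a risk model with the FIT rule
# across all achievable sensitivities.

# Confusion counts along the descending-score sweep at each distinct
# threshold: TP, FP, n_pos (cumulative), for score >= threshold.
score_sweep <- function(score, y) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  tp <- cumsum(y[ord])
  fp <- cumsum(1 - y[ord])
  idx <- which(!duplicated(s, fromLast = TRUE))
  data.frame(threshold = s[idx], tp = tp[idx], fp = fp[idx])
}

#' ROC curve and c-statistic
#'
#' The ROC curve is the threshold sweep over distinct scores, interpolated
#' linearly between points. The c-statistic is computed as the concordance
#' probability by rank statistics, with tied scores counted 1/2 — this makes
#' the tie convention explicit, and equals the trapezoidal area under the
#' linearly interpolated ROC curve by construction.
#'
#' @param scores a [risk_scores()] data frame (`fit` optional here: any
#'   data frame with `risk` and `y` works).
#' @return list with `curve` (`data.frame` of `threshold`, `fpr`, `tpr`) and
#'   `c_statistic` (percent).
#' @examples
#' s <- data.frame(risk = c(.9, .7, .4, .2), y = c(1, 0, 1, 0))
#' roc_and_cstat(s)$c_statistic  # 75
#' @export
roc_and_cstat <- function(scores) {
  check_scores(scores, "roc_and_cstat", require_fit = FALSE)
  y <- scores$y
  r <- scores$risk
  sw <- score_sweep(r, y)
  P <- sum(y == 1); N <- sum(y == 0)
  curve <- data.frame(threshold = c(Inf, sw$threshold),
                      fpr = c(0, sw$fp / N),
                      tpr = c(0, sw$tp / P))
  # Wilcoxon-Mann-Whitney concordance with mid-ranks (ties count 1/2)
  cstat <- (sum(rank(r)[y == 1]) - P * (P + 1) / 2) / (P * N)
  list(curve = curve, c_statistic = 100 * cstat)
}

# Corner set of the precision-recall curve: distinct-threshold sweep with
# recall ties collapsed to the maximum-precision corner (smallest FP at each
# TP, i.e. the first corner of each TP block along the sweep).
pr_corners <- function(score, y) {
  sw <- score_sweep(score, y)
  keep <- !duplicated(sw$tp)          # first corner per TP = min FP
  corners <- sw[keep & sw$tp > 0, , drop = FALSE]
  rbind(data.frame(threshold = Inf, tp = 0, fp = 0), corners)
}

#' Precision-recall curve with Davis-Goadrich interpolation
#'
#' Corner points are taken at each distinct score threshold (recall ties
#' collapsed to the maximum-precision corner). Between consecutive corners
#' A and B, the false-positive count at intermediate integer true-positive
#' counts is interpolated linearly,
#' `FP(TP) = FP_A + (FP_B - FP_A) * (TP - TP_A) / (TP_B - TP_A)`,
#' which is the achievable performance of classifiers mixing A and B; the
#' curve therefore has one point per integer TP from 1 to the number of
#' cases.
#'
#' @param scores data frame with `risk` and `y` (use column `fit` as `risk`
#'   to obtain the FIT test's curve).
#' @return `data.frame` of class `pr_curve`: `tp`, `fp`, `recall`,
#'   `precision`, `threshold` (`NA` on interpolated points).
#' @export
pr_curve_davis_goadrich <- function(scores) {
  check_scores(scores, "pr_curve_davis_goadrich", require_fit = FALSE)
  y <- scores$y
  P <- sum(y == 1)
  corners <- pr_corners(scores$risk, y)
  tp_grid <- seq_len(P)
  fp <- stats::approx(corners$tp, corners$fp, xout = tp_grid,
                      method = "linear")$y
  thr <- corners$threshold[match(tp_grid, corners$tp)]
  out <- data.frame(tp = tp_grid, fp = fp, recall = tp_grid / P,
                    precision = tp_grid / (tp_grid + fp), threshold = thr)
  class(out) <- c("pr_curve", class(out))
  attr(out, "n") <- nrow(scores)
  attr(out, "prevalence") <- P / nrow(scores)
  out
}

#' Average precision
#'
#' Step-sum estimator of the area under the precision-recall curve over the
#' descending-score sweep: `sum_k (R_k - R_{k-1}) * P_k`, reported in
#' percent. For a random ranking it estimates the outcome prevalence; for a
#' perfect ranking it is 100.
#'
#' @param scores data frame with `risk` and `y`.
#' @return average precision, percent.
#' @examples
#' s <- data.frame(risk = c(.9, .8, .7, .6), y = c(1, 0, 1, 0))
#' average_precision(s)  # 83.33
#' @export
average_precision <- function(scores) {
  check_scores(scores, "average_precision", require_fit = FALSE)
  sw <- score_sweep(scores$risk, scores$y)
  P <- sum(scores$y == 1)
  recall <- sw$tp / P
  precision <- sw$tp / (sw$tp + sw$fp)
  100 * sum(diff(c(0, recall)) * precision)
}

#' Test-reduction curve
#'
#' For each achievable sensitivity, compares the positive predictive value
#' of the FIT rule with the model operated at its matched-sensitivity
#' threshold (capturing at least as many cancers with as few positives as
#' possible), via `reduction = (ppv_fit / ppv_model - 1) * 100`. Negative
#' values mean the model needs fewer positive tests at equal sensitivity.
#'
#' The sensitivity grid is the set of FIT operating points at which a new
#' cancer is captured (thresholds equal to observed cancer FIT values), so
#' both tests sit on a recall-achieving corner of their sweep and a model
#' that is a monotone transform of FIT yields an identically zero curve.
#' The conventional referral threshold is always added to the grid, so the
#' curve contains the operating point of [referral_reduction()] exactly.
#'
#' @param scores a [risk_scores()] data frame.
#' @param fit_threshold conventional FIT referral threshold, default 10.
#' @return `data.frame` with `fit_threshold`, `sensitivity` (percent),
#'   `ppv_fit`, `ppv_model`, `n_pos_fit`, `n_pos_model`, `reduction`
#'   (percent). Points where the model PPV is zero are omitted.
#' @export
test_reduction_curve <- function(scores, fit_threshold = 10) {
  check_scores(scores, "test_reduction_curve")
  y <- scores$y
  P <- sum(y == 1)
  thr_grid <- sort(unique(c(scores$fit[y == 1], fit_threshold)),
                   decreasing = TRUE)
  sweep_m <- risk_sweep(scores$risk, y)
  rows <- lapply(thr_grid, function(t) {
    pos_f <- scores$fit >= t
    tp_f <- sum(pos_f & y == 1)
    if (tp_f == 0L) return(NULL)
    n_pos_f <- sum(pos_f)
    ok <- sweep_m$tp >= tp_f
    u <- max(sweep_m$threshold[ok])
    i <- match(u, sweep_m$threshold)
    ppv_m <- sweep_m$tp[i] / sweep_m$n_pos[i]
    if (ppv_m == 0) return(NULL)
    ppv_f <- tp_f / n_pos_f
    data.frame(fit_threshold = t, sensitivity = 100 * tp_f / P,
               ppv_fit = ppv_f, ppv_model = ppv_m,
               n_pos_fit = n_pos_f, n_pos_model = sweep_m$n_pos[i],
               reduction = (ppv_f / ppv_m - 1) * 100)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
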