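# Bootstrap percentile confidence intervals and Wilson score intervals.

#' Bootstrap percentile confidence interval for a cohort metric
#'
#' Resamples patients with replacement (same size as the original cohort),
#' recomputes the metric on every replicate - including any internal
#' threshold re-selection, so selection uncertainty is captured - and
#' returns percentile bounds taken as order statistics of the replicate
#' values (no normal approximation). Replicates on which the metric is
#' undefined because a single outcome class was drawn are redrawn up to 10
#' times and then counted as failures; more than 5% failures is an error.
#'
#' @param metric function taking a data frame and returning a single
#'   numeric value.
#' @param data the cohort-level data frame to resample rows of.
#' @param B number of bootstrap replicates, default 1000.
#' @param level coverage in percent, default 95.
#' @param seed integer seed; resampling is deterministic given it.
#' @param stratify optional column name; when given, resampling is
#'   stratified within the levels of that column (useful for rare events).
#' @return object of class `bootstrap_estimate`: list with `estimate`,
#'   `lower`, `upper`, `B`, `level`, `n_failed`, `replicates`, and
#'   `significant_reduction` (`TRUE` when the interval excludes zero;
#'   negative values indicate reductions in, positive values increases in
#'   referrals when the metric is a referral change).
#' @examples
#' d <- data.frame(x = rnorm(100))
#' bootstrap_ci(function(d) mean(d$x), d, B = 200, seed = 1)
#' @export
bootstrap_ci <- function(metric, data, B = 1000, level = 95, seed,
                         stratify = NULL) {
  if (missing(seed)) {
    fv_stop("bootstrap_ci: seed is required for reproducible resampling",
            "fitvalid_parameter_error")
  }
  if (B < 1) fv_stop("bootstrap_ci: B must be >= 1", "fitvalid_parameter_error")
  est <- metric(data)
  n <- nrow(data)
  idx_groups <- if (is.null(stratify)) NULL else split(seq_len(n), data[[stratify]])
  reps <- rep(NA_real_, B)
  failures <- character(0)
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (attempt in seq_len(10L)) {
        idx <- if (is.null(idx_groups)) {
          sample.int(n, n, replace = TRUE)
        } else {
          unlist(lapply(idx_groups, function(g) {
            g[sample.int(length(g), length(g), replace = TRUE)]
          }), use.names = FALSE)
        }
        val <- tryCatch(metric(data[idx, , drop = FALSE]),
                        error = function(e) e)
        if (!inherits(val, "error")) break
      }
      if (inherits(val, "error")) {
        failures <- c(failures, conditionMessage(val))
      } else {
        reps[b] <- val
      }
    }
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.05 * B) {
    fv_stop(sprintf(
      "bootstrap_ci: metric failed on %d/%d replicates; e.g.: %s",
      n_failed, B, failures[1]), "fitvalid_bootstrap_error")
  }
  good <- reps[!is.na(reps)]
  alpha <- (100 - level) / 200
  bounds <- stats::quantile(good, c(alpha, 1 - alpha), type = 1, names = FALSE)
  structure(list(estimate = est, lower = bounds[1], upper = bounds[2],
                 B = B, level = level, n_failed = n_failed,
                 replicates = good,
                 significant_reduction = bounds[1] > 0 | bounds[2] < 0,
                 sign_convention = "negative values indicate reductions in, positive values increases in referrals"),
            class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("%.4g (%d%% percentile CI [%.4g, %.4g], B = %d%s)\n",
              x$estimate, x$level, x$lower, x$upper, x$B,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Wilson score interval for a proportion
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param level coverage in percent, default 95.
#' @return numeric vector `c(lower, upper)`, both in `[0, 1]`; the interval
#'   always contains `k/n`.
#' @examples
#' wilson_ci(0, 10)  # c(0, 0.278)
#' @export
wilson_ci <- function(k, n, level = 95) {
  if (n <= 0) fv_stop("wilson_ci: n must be positive", "fitvalid_domain_error")
  if (k < 0 || k > n) {
    fv_stop("wilson_ci: k must lie in [0, n]", "fitvalid_domain_error")
  }
  z <- stats::qnorm(1 - (100 - level) / 200)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  # boundary cases are exact (floating arithmetic can stray by ~1e-17)
  lower <- if (k == 0) 0 else max(0, centre - half)
  upper <- if (k == n) 1 else min(1, centre + half)
  c(lower = lower, upper = upper)
}
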