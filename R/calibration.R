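# Calibration metrics, LOWESS calibration curves, three recalibration
# methods and the FIT-spline comparator model.

#' Overall calibration summary
#'
#' Event rate, mean predicted risk, observed/expected ratio
#' (`mean(y)/mean(p)`; values above 1 mean the model under-predicts), and
#' the intercept and slope of a logistic regression of the outcome on the
#' logit of the predicted probabilities (ideal 0 and 1). Intercept and
#' slope are estimated jointly by maximum likelihood; set
#' `fixed_slope = TRUE` to fix the slope at 1 and estimate the intercept as
#' an offset model.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities in (0, 1); clipped to
#'   `[1e-10, 1 - 1e-10]` before the logit.
#' @param fixed_slope logical, default `FALSE`.
#' @return one-row `data.frame` of class `calibration_summary`:
#'   `event_rate` (%), `mean_risk` (%), `oe_ratio`, `logistic_intercept`,
#'   `logistic_slope`, `degenerate` (TRUE when the predictor is constant, in
#'   which case intercept/slope are `NA`).
#' @examples
#' y <- rep(c(1, 0), c(128, 9872)); p <- rep(0.0084, 10000)
#' calibration_summary(y, p)$oe_ratio  # 1.52
#' @export
calibration_summary <- function(y, p, fixed_slope = FALSE) {
  stopifnot(length(y) == length(p))
  if (any(p <= 0 | p >= 1)) {
    fv_stop("calibration_summary: probabilities must lie strictly in (0, 1)",
            "fitvalid_domain_error")
  }
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    fv_stop("calibration_summary: y must be binary with both classes present",
            "fitvalid_degenerate_error")
  }
  lp <- stats::qlogis(clip_prob(p))
  degenerate <- stats::var(lp) < .Machine$double.eps
  if (degenerate) {
    warning("calibration_summary: constant predicted probability; slope undefined")
    intercept <- NA_real_
    slope <- NA_real_
  } else if (fixed_slope) {
    fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
    intercept <- unname(stats::coef(fit)[1])
    slope <- 1
  } else {
    fit <- stats::glm(y ~ lp, family = stats::binomial())
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  out <- data.frame(event_rate = 100 * mean(y), mean_risk = 100 * mean(p),
                    oe_ratio = mean(y) / mean(p),
                    logistic_intercept = intercept, logistic_slope = slope,
                    degenerate = degenerate)
  class(out) <- c("calibration_summary", class(out))
  out
}

#' LOWESS calibration curve
#'
#' Locally weighted regression of the binary outcome on the predicted
#' probability, evaluated over the sorted predictions and clipped to
#' `[0, 1]`. Robustness iterations are disabled (`iter = 0`): with a binary
#' response, the re-weighting step would treat the rare events as outliers
#' and flatten the curve. A well-calibrated model tracks the diagonal.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities.
#' @param frac LOWESS smoother span, default 0.3.
#' @return `data.frame` with `p` (sorted) and `observed` (smoothed event
#'   rate).
#' @export
lowess_calibration_curve <- function(y, p, frac = 0.3) {
  stopifnot(length(y) == length(p))
  if (length(y) < 50L) {
    fv_stop("lowess_calibration_curve: needs n >= 50; use grouped calibration for smaller samples",
            "fitvalid_parameter_error")
  }
  sm <- stats::lowess(p, y, f = frac, iter = 0)
  data.frame(p = sm$x, observed = pmin(pmax(sm$y, 0), 1))
}

#' Rescale FIT values by a constant
#'
#' Multiplies FIT values by `k`, optionally re-capping at the reporting
#' limit. Used to recalibrate a model derived where FIT values ran higher:
#' when `k` is `NULL` it is estimated by [estimate_fit_scale()] so that the
#' share of rescaled values at or above `fit_threshold` matches
#' `target_share`.
#'
#' @param fit reported FIT values.
#' @param k positive scale factor, or `NULL` to estimate.
#' @param target_share reference share of values `>= fit_threshold`
#'   (required when `k` is `NULL`).
#' @param fit_threshold threshold defining the share, default 10.
#' @param cap optional upper cap applied after scaling (e.g. 400); default
#'   `NULL` (no cap, as for model input).
#' @return rescaled values, with the factor attached as attribute `"k"`.
#' @export
recalibrate_fit_scale <- function(fit, k = NULL, target_share = NULL,
                                  fit_threshold = 10, cap = NULL) {
  if (is.null(k)) {
    if (is.null(target_share)) {
      fv_stop("recalibrate_fit_scale: supply k or target_share",
              "fitvalid_parameter_error")
    }
    k <- estimate_fit_scale(fit, target_share, fit_threshold)
  }
  if (k <= 0) {
    fv_stop("recalibrate_fit_scale: k must be positive",
            "fitvalid_domain_error")
  }
  out <- k * fit
  if (!is.null(cap)) out <- pmin(out, cap)
  attr(out, "k") <- k
  out
}

#' Estimate the FIT scale factor matching a reference positivity
#'
#' One-dimensional search over the achievable positivity shares: the share
#' of `k * fit >= fit_threshold` is a step function of `k` with steps at
#' `fit_threshold / x` for observed positive values `x`, so the candidate
#' minimising the distance to `target_share` is found by scanning the
#' distinct observed values.
#'
#' @inheritParams recalibrate_fit_scale
#' @return the scale factor `k`.
#' @export
estimate_fit_scale <- function(fit, target_share, fit_threshold = 10) {
  if (target_share < 0 || target_share > 1) {
    fv_stop("estimate_fit_scale: target_share must lie in [0, 1]",
            "fitvalid_domain_error")
  }
  cand <- sort(unique(fit[fit > 0]))
  if (length(cand) == 0L) {
    fv_stop("estimate_fit_scale: no positive FIT values to scale",
            "fitvalid_degenerate_error")
  }
  shares <- vapply(cand, function(c) mean(fit >= c), numeric(1))
  c_best <- cand[which.min(abs(shares - target_share))]
  fit_threshold / c_best
}

#' Reference FIT distribution
#'
#' An empirical distribution summary used as the target of quantile
#' recalibration: a sorted value grid with nondecreasing cumulative
#' probabilities ending at 1.
#'
#' @param values sorted FIT values, or a raw sample via `sample=`.
#' @param cum_prob cumulative probabilities matching `values`.
#' @param sample alternatively, a raw reference sample from which the
#'   empirical grid (`i/n`) is built.
#' @return `data.frame` of class `reference_fit_distribution` with columns
#'   `value`, `cum_prob`.
#' @export
reference_fit_distribution <- function(values = NULL, cum_prob = NULL,
                                       sample = NULL) {
  if (!is.null(sample)) {
    values <- sort(sample)
    cum_prob <- seq_along(values) / length(values)
  }
  if (length(values) < 2L) {
    fv_stop("reference_fit_distribution: at least 2 support points required",
            "fitvalid_config_error")
  }
  if (is.unsorted(values) || is.unsorted(cum_prob) ||
      abs(cum_prob[length(cum_prob)] - 1) > 1e-8) {
    fv_stop("reference_fit_distribution: values and cum_prob must be nondecreasing with cum_prob ending at 1",
            "fitvalid_config_error")
  }
  out <- data.frame(value = values, cum_prob = cum_prob)
  # collapse duplicated probability levels, keeping the largest value
  out <- out[!duplicated(out$cum_prob, fromLast = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reference_fit_distribution", class(out))
  out
}

#' Synthetic reference FIT distribution of a derivation population
#'
#' A reconstruction of a model-derivation FIT distribution from published
#' summaries only (median 4, quartiles 4 and 8, 22.4% of values at or above
#' 10 ug/g, reporting range from below 4 up to tens of thousands): a
#' lognormal with the validation data's log-scale spread, anchored so that
#' the share above 10 ug/g is 22.4%, floored at 4 (the derivation minimum)
#' and capped at 69,800. This object is synthetic - the real distribution
#' is not public - and is intended for demonstrations and tests of the
#' quantile-recalibration mechanics.
#'
#' @param sdlog log-scale spread, defaulting to the validation FIT tail's.
#' @return a [reference_fit_distribution()].
#' @export
reference_fit_synthetic_derivation <- function(sdlog = 2.3904) {
  p10 <- 0.224
  meanlog <- log(10) - sdlog * stats::qnorm(1 - p10)
  probs <- seq(0.001, 0.999, by = 0.001)
  vals <- pmin(pmax(stats::qlnorm(probs, meanlog, sdlog), 4), 69800)
  reference_fit_distribution(values = c(vals, 69800),
                             cum_prob = c(probs, 1))
}

#' Quantile recalibration of FIT values
#'
#' Maps each value through the source empirical CDF (mid-ranks for ties,
#' `u = rank/n`) and then through the inverse reference CDF (linear
#' interpolation between grid points, clipped to the reference range), so
#' the transformed values' distribution matches the reference population's.
#' Tied source values (e.g. the zero-inflated mass) map to a single
#' reference quantile.
#'
#' @param fit source FIT values.
#' @param ref a [reference_fit_distribution()].
#' @return transformed FIT values.
#' @export
recalibrate_fit_quantile <- function(fit, ref) {
  if (!inherits(ref, "reference_fit_distribution")) {
    ref <- reference_fit_distribution(values = ref$value,
                                      cum_prob = ref$cum_prob)
  }
  u <- rank(fit, ties.method = "average") / length(fit)
  stats::approx(ref$cum_prob, ref$value, xout = u, rule = 2,
                ties = "ordered")$y
}

# Ridge-penalised logistic fit of y on a single covariate, used as the
# fallback under separation. Newton iterations on (intercept, slope) with a
# small L2 penalty on the slope.
ridge_logistic <- function(y, x, lambda = 1e-3, iters = 50L) {
  beta <- c(stats::qlogis(clip_prob(mean(y))), 1)
  X <- cbind(1, x)
  for (i in seq_len(iters)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- crossprod(X, y - mu) - c(0, lambda * beta[2])
    H <- crossprod(X * w, X) + diag(c(1e-12, lambda))
    step <- solve(H, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Logistic recalibration
#'
#' Fits the calibration intercept and slope of the supplied probabilities
#' and returns the mapping
#' `p' = plogis(a + b * qlogis(p))`. Refitting the calibration summary on
#' the recalibrated probabilities of the same data gives intercept ~0 and
#' slope ~1; applying the recalibration twice changes the coefficients only
#' by estimation noise. Under separation a ridge-penalised fit is used with
#' a warning.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities.
#' @return a function mapping probabilities to recalibrated probabilities,
#'   with attribute `"coefficients"` (`intercept`, `slope`).
#' @export
logistic_recalibration <- function(y, p) {
  lp <- stats::qlogis(clip_prob(p))
  if (stats::var(lp) < .Machine$double.eps) {
    fv_stop("logistic_recalibration: constant predicted probability; recalibration degenerate",
            "fitvalid_degenerate_error")
  }
  coefs <- withCallingHandlers(
    {
      fit <- stats::glm(y ~ lp, family = stats::binomial())
      stats::coef(fit)
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fit_sep <- !all(is.finite(coefs)) || abs(coefs[2]) > 1e3
  if (fit_sep) {
    warning("logistic_recalibration: separation detected; using penalized fit")
    coefs <- ridge_logistic(y, lp)
  }
  a <- unname(coefs[1]); b <- unname(coefs[2])
  f <- function(p) stats::plogis(a + b * stats::qlogis(clip_prob(p)))
  attr(f, "coefficients") <- c(intercept = a, slope = b)
  f
}

#' FIT-spline comparator model
#'
#' A logistic model predicting cancer from a natural cubic spline basis of
#' `log(fit + 1)`, covering every possible FIT threshold so the FIT value
#' itself can be compared against richer models in calibration and decision
#' curve analyses. Knots sit at the 5/35/65/95% quantiles of `log(fit + 1)`;
#' on zero-inflated FIT data the lower quantiles routinely coincide at zero
#' and the duplicated knots are collapsed silently (fewer effective knots is
#' the expected behaviour there, not an anomaly). Only genuine degeneracy -
#' fewer than two distinct knots left - draws a warning, and a constant FIT
#' column degrades to an intercept-only model returning the prevalence.
#'
#' @param fit reported FIT values.
#' @param y binary outcomes.
#' @param knot_quantiles quantile positions of the knots.
#' @return object of class `fit_spline_model` with a `predict` method
#'   mapping FIT values to probabilities.
#' @export
fit_spline_model <- function(fit, y, knot_quantiles = c(5, 35, 65, 95) / 100) {
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    fv_stop("fit_spline_model: y must be binary with both classes present",
            "fitvalid_degenerate_error")
  }
  x <- log(fit + 1)
  kn <- unique(stats::quantile(x, knot_quantiles, names = FALSE))
  if (length(unique(x)) < 2L || length(kn) < 2L) {
    if (length(unique(x)) >= 2L) {
      warning("fit_spline_model: knot quantiles degenerate; falling back to intercept-only model")
    }
    model <- stats::glm(y ~ 1, family = stats::binomial())
    basis <- NULL
  } else {
    boundary <- range(kn)
    inner <- kn[kn > boundary[1] & kn < boundary[2]]
    basis <- list(inner = inner, boundary = boundary)
    B <- splines::ns(x, knots = inner, Boundary.knots = boundary)
    model <- stats::glm(y ~ B, family = stats::binomial())
  }
  structure(list(model = model, basis = basis), class = "fit_spline_model")
}

#' @param object a `fit_spline_model`.
#' @param fit new FIT values to predict for.
#' @param ... unused.
#' @rdname fit_spline_model
#' @export
predict.fit_spline_model <- function(object, fit, ...) {
  if (is.null(object$basis)) {
    return(rep(stats::plogis(stats::coef(object$model)[[1]]), length(fit)))
  }
  x <- log(fit + 1)
  B <- splines::ns(x, knots = object$basis$inner,
                   Boundary.knots = object$basis$boundary)
  eta <- stats::coef(object$model)[1] + drop(B %*% stats::coef(object$model)[-1])
  clip_prob(stats::plogis(eta))
}
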