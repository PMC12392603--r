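#' Surrogate logistic risk model linking predictors to cancer probability
#'
#' The validation pipeline is model-agnostic: any function that maps a
#' patient record to a cancer probability can be evaluated. For synthetic
#' cohorts the outcome is generated from a known logistic surrogate on the
#' five predictors used by FIT-based triage models in this field: reported
#' FIT (log scale), age, sex, platelet count and mean cell volume. Knowing
#' the generating model makes parameter-recovery checks possible (scoring a
#' cohort with its own generator must look calibrated).
#'
#' @param intercept intercept of the linear predictor (logit scale).
#' @param log_fit coefficient on `log(fit_reported + 1)` (fit in ug Hb/g).
#' @param age coefficient per year of age.
#' @param male coefficient for male sex (indicator).
#' @param plt coefficient per 10^9/L platelet count.
#' @param mcv coefficient per fL mean cell volume.
#' @return an object of class `surrogate_model`.
#' @seealso [true_risk()], [default_surrogate_model()]
#' @export
surrogate_model <- function(intercept, log_fit, age, male, plt, mcv) {
  coefs <- c(intercept = intercept, log_fit = log_fit, age = age,
             male = male, plt = plt, mcv = mcv)
  if (any(!is.finite(coefs))) {
    fv_stop("surrogate_model: all coefficients must be finite",
            "fitvalid_parameter_error")
  }
  structure(list(coefficients = coefs), class = "surrogate_model")
}

#' Default surrogate model coefficients
#'
#' Coefficients were fixed once, by simulation against the marginal predictor
#' distributions used by [synthetic_params()], so that a generated cohort has
#' roughly 1.3% cancer prevalence and the FIT >= 10 ug/g rule detects roughly
#' 88% of cancers. Directions follow clinical expectation: risk increases
#' with FIT, age, male sex and platelet count, and decreases with mean cell
#' volume (microcytosis accompanies occult bleeding).
#'
#' @return a `surrogate_model`.
#' @export
default_surrogate_model <- function() {
  surrogate_model(intercept = -5.215, log_fit = 0.95, age = 0.028,
                  male = 0.25, plt = 0.0025, mcv = -0.045)
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("Surrogate logistic risk model\n")
  cat("  logit(p) = b0 + b1*log(fit+1) + b2*age + b3*male + b4*plt + b5*mcv\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Cancer probability under a surrogate model
#'
#' Inverse-logit of the model's linear predictor, evaluated on one or more
#' patient records. Probabilities are strictly inside (0, 1).
#'
#' @param model a [surrogate_model()].
#' @param record a data.frame (or list) with columns/fields `fit_value`,
#'   `age`, `sex` (`"male"` or `"female"`), `plt`, `mcv`.
#' @return numeric vector of probabilities in (0, 1).
#' @examples
#' m <- surrogate_model(0, 0, 0, 0, 0, 0)
#' true_risk(m, data.frame(fit_value = 0, age = 60, sex = "male",
#'                         plt = 250, mcv = 90))  # 0.5
#' @export
true_risk <- function(model, record) {
  stopifnot(inherits(model, "surrogate_model"))
  record <- as.data.frame(record)
  check_columns(record, c("fit_value", "age", "sex", "plt", "mcv"),
                "true_risk")
  needed <- record[, c("fit_value", "age", "plt", "mcv")]
  if (any(is.na(needed)) || any(is.na(record$sex))) {
    fv_stop("true_risk: missing predictor value(s); all of fit_value, age, sex, plt, mcv are required",
            "fitvalid_missing_data_error")
  }
  if (any(record$fit_value < 0)) {
    fv_stop("true_risk: fit_value must be non-negative", "fitvalid_domain_error")
  }
  b <- model$coefficients
  male <- as.numeric(record$sex == "male")
  lp <- b[["intercept"]] +
    b[["log_fit"]] * log(record$fit_value + 1) +
    b[["age"]] * record$age +
    b[["male"]] * male +
    b[["plt"]] * record$plt +
    b[["mcv"]] * record$mcv
  clip_prob(stats::plogis(lp))
}
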