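# Fixtures built in code: small score sets and random cohorts.

# The 8-patient worked example used across the threshold and curve tests.
toy_scores <- function() {
  risk_scores(risk = c(.9, .8, .7, .6, .5, .4, .3, .2),
              fit  = c(200, 15, 12, 3, 11, 2, 1, 0),
              y    = c(1, 1, 0, 1, 0, 0, 0, 0))
}

# Random score set with continuous risks, zero-inflated FIT and outcome
# linked to both, for property-style tests.
random_scores <- function(n, prevalence = 0.2, link = 1.5) {
  u <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(prevalence) + link * u))
  fit <- ifelse(stats::runif(n) < 0.5, 0,
                pmin(stats::rlnorm(n, 2 + 0.8 * u, 1.5), 400))
  risk <- stats::plogis(stats::qlogis(prevalence) + link * u +
                          stats::rnorm(n, 0, 0.5))
  risk_scores(risk = risk, fit = fit, y = y)
}

# Exhaustive-enumeration oracle for the matched-sensitivity threshold:
# scan every distinct observed risk value and pick the largest threshold
# whose cancer count matches (or, failing exact equality, is at least) the
# FIT rule's cancer count, breaking count ties toward fewer positives.
oracle_matched_threshold <- function(scores, fit_threshold = 10) {
  tstar <- sum(scores$y == 1 & scores$fit >= fit_threshold)
  if (tstar == 0) return(NULL)
  cand <- sort(unique(scores$risk), decreasing = TRUE)
  tp <- vapply(cand, function(t) sum(scores$y == 1 & scores$risk >= t),
               numeric(1))
  exact <- cand[tp == tstar]
  if (length(exact) > 0) return(max(exact))
  max(cand[tp >= tstar])
}
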