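# Decision-curve analysis: net benefit of treating (referring) patients
# whose predicted risk exceeds a threshold probability.

#' Net benefit at a threshold probability
#'
#' `NB(t) = TP/n - FP/n * t / (1 - t)` for the rule `p >= t`: the benefit of
#' true referrals minus false referrals weighted by the odds of the
#' threshold probability. The treat-none strategy has net benefit 0
#' everywhere; treat-all crosses 0 at the outcome prevalence.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities (a constant 1 encodes treat-all).
#' @param t threshold probability or vector of thresholds, each in (0, 1).
#' @return numeric vector of net benefit values, one per threshold.
#' @examples
#' y <- rep(c(1, 0), c(5, 95))
#' net_benefit(y, rep(1, 100), t = 0.05)  # treat-all at prevalence: 0
#' @export
net_benefit <- function(y, p, t) {
  if (any(t <= 0 | t >= 1)) {
    fv_stop("net_benefit: thresholds must lie in (0, 1)",
            "fitvalid_domain_error")
  }
  stopifnot(length(y) == length(p))
  n <- length(y)
  vapply(t, function(ti) {
    pos <- p >= ti
    tp <- sum(pos & y == 1)
    fp <- sum(pos & y == 0)
    tp / n - (ti / (1 - ti)) * fp / n
  }, numeric(1))
}

#' Decision curves for a set of strategies
#'
#' Net benefit across a threshold grid for each named probability set, with
#' treat-all and treat-none reference strategies added automatically.
#' Recalibrated model variants are simply additional strategies. The
#' default grid spans 0.2% to 5% risk in 0.1% steps - the clinically
#' relevant band around the cancer probabilities at which FIT-based
#' referral operates.
#'
#' @param y binary outcomes.
#' @param strategies named list of probability vectors (each the length of
#'   `y`).
#' @param grid threshold grid inside (0, 1).
#' @return long `data.frame` with `threshold`, `strategy`, `net_benefit`.
#' @export
decision_curves <- function(y, strategies,
                            grid = seq(0.002, 0.05, by = 0.001)) {
  if (any(grid <= 0 | grid >= 1)) {
    fv_stop("decision_curves: grid must lie inside (0, 1)",
            "fitvalid_domain_error")
  }
  bad <- vapply(strategies, function(p) length(p) != length(y), logical(1))
  if (any(bad)) {
    fv_stop(sprintf("decision_curves: strategy length mismatch: %s",
                    paste(names(strategies)[bad], collapse = ", ")),
            "fitvalid_schema_error")
  }
  all_strat <- c(strategies,
                 list(treat_all = rep(1, length(y)),
                      treat_none = rep(1e-12, length(y))))
  rows <- lapply(names(all_strat), function(nm) {
    data.frame(threshold = grid, strategy = nm,
               net_benefit = net_benefit(y, all_strat[[nm]], grid))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
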