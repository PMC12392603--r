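# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip probabilities away from 0 and 1
#'
#' Predicted probabilities are clipped to `[eps, 1 - eps]` before any logit
#' transform so that calibration fits remain finite.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping tolerance; default `1e-10`.
#' @return clipped numeric vector.
#' @keywords internal
clip_prob <- function(p, eps = 1e-10) {
  pmin(pmax(p, eps), 1 - eps)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All randomised package code funnels through
# this so that no function mutates the global stream as a side effect.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# stop() with a consistent error class so tests can assert on failures
# without matching message text.
fv_stop <- function(msg, class) {
  stop(structure(class = c(class, "fitvalid_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Check that a cohort-like data.frame has the named columns.
check_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    fv_stop(sprintf("%s: missing required column(s): %s",
                    where, paste(missing, collapse = ", ")),
            "fitvalid_schema_error")
  }
  invisible(df)
}

# Validate a risk/fit/outcome score set used throughout the threshold,
# discrimination and calibration modules.
check_scores <- function(scores, where, require_fit = TRUE,
                         require_both_classes = TRUE) {
  cols <- c("risk", "y")
  if (require_fit) cols <- c("risk", "fit", "y")
  check_columns(scores, cols, where)
  if (any(!scores$y %in% c(0, 1))) {
    fv_stop(sprintf("%s: outcome y must be binary 0/1", where),
            "fitvalid_domain_error")
  }
  if (any(scores$risk <= 0 | scores$risk > 1)) {
    fv_stop(sprintf("%s: risk must lie in (0, 1]", where),
            "fitvalid_domain_error")
  }
  if (require_both_classes &&
      (sum(scores$y == 1) == 0L || sum(scores$y == 0) == 0L)) {
    fv_stop(sprintf("%s: both outcome classes must be present", where),
            "fitvalid_degenerate_error")
  }
  invisible(scores)
}

#' Assemble a risk score set
#'
#' Bundles per-patient model risks, reported FIT values and binary cancer
#' outcomes into the data frame layout expected by the threshold-selection,
#' discrimination and calibration functions.
#'
#' @param risk predicted probabilities in (0, 1].
#' @param fit reported FIT values in ug Hb/g, in `[0, 400]`.
#' @param y binary cancer outcome (0/1).
#' @return a `data.frame` with columns `risk`, `fit`, `y`.
#' @examples
#' s <- risk_scores(risk = c(.9, .2), fit = c(120, 0), y = c(1, 0))
#' @export
risk_scores <- function(risk, fit, y) {
  if (length(risk) != length(y) || length(fit) != length(y)) {
    fv_stop("risk_scores: risk, fit and y must have equal length",
            "fitvalid_schema_error")
  }
  scores <- data.frame(risk = as.numeric(risk), fit = as.numeric(fit),
                       y = as.integer(y))
  check_scores(scores, "risk_scores", require_both_classes = FALSE)
  scores
}
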