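#!/usr/bin/env Rscript
# Step 4: discrimination - ROC, precision-recall and test-reduction curves.
#
# Computes the c-statistic and average precision for the risk model and for
# the FIT value used as a score, per period and overall, and exports the
# three curve families for the whole cohort.

suppressPackageStartupMessages(library(fitvalid))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

coh <- read_cohort("results/prepared_cohort.csv")
model <- scenario_sixperiod(seed = seed)$model
risk <- true_risk(model, coh)
scores <- risk_scores(risk, coh$fit_value, coh$crc)

labels <- c("All data", setdiff(unique(coh$period), "unassigned"))
rows <- lapply(labels, function(lab) {
  idx <- if (lab == "All data") seq_len(nrow(coh)) else which(coh$period == lab)
  s <- scores[idx, ]
  f <- data.frame(risk = pmin(pmax(s$fit / 401, 1e-6), 1 - 1e-6), y = s$y)
  data.frame(period = lab,
             c_statistic_model = roc_and_cstat(s)$c_statistic,
             c_statistic_fit = roc_and_cstat(f)$c_statistic,
             average_precision_model = average_precision(s),
             average_precision_fit = average_precision(f))
})
disc <- do.call(rbind, rows)
utils::write.csv(disc, "results/discrimination.csv", row.names = FALSE)

utils::write.csv(roc_and_cstat(scores)$curve, "results/curve_roc.csv",
                 row.names = FALSE)
utils::write.csv(pr_curve_davis_goadrich(scores), "results/curve_pr.csv",
                 row.names = FALSE)
utils::write.csv(test_reduction_curve(scores),
                 "results/curve_test_reduction.csv", row.names = FALSE)

print(disc)
cat("Wrote results/discrimination.csv and curve CSVs\n")
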