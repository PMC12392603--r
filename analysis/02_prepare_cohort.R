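#!/usr/bin/env Rscript
# Step 2: prepare the cohort for validation.
#
# Applies the preparation rules to results/cohort.csv: inclusion/exclusion
# criteria in order (non-GP request, under-18, insufficient follow-up,
# prior cancer, missing bloods), outcome definition within the 180-day
# follow-up window, and period assignment. Writes the prepared cohort and
# the exclusion tally. With the clean simulated cohort the tally is all
# zeros; rerun 01 with contamination fractions to exercise it.

suppressPackageStartupMessages(library(fitvalid))
args <- commandArgs(trailingOnly = TRUE)
followup <- if (length(args) >= 1) as.integer(args[1]) else 180L

cohort <- read_cohort("results/cohort.csv")
prep <- prepare_cohort(cohort, followup_days = followup)
write_cohort(prep$cohort, "results/prepared_cohort.csv")
utils::write.csv(data.frame(criterion = names(prep$tally),
                            n_removed = as.integer(prep$tally)),
                 "results/exclusion_tally.csv", row.names = FALSE)

print(prep$tally)
print(cohort_summary(prep$cohort))
cat("Wrote results/prepared_cohort.csv and results/exclusion_tally.csv\n")
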