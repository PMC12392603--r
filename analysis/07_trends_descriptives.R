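#!/usr/bin/env Rscript
# Step 7: monthly trends and descriptive tests.
#
# Monthly FIT positivity with Wilson intervals (months with fewer than 10
# positive events suppressed), the regression of monthly positivity on
# monthly testing volume over the rising-volume window, and the standard
# descriptive comparisons between cancer and non-cancer patients
# (chi-square for categorical predictors, Mann-Whitney U for continuous).

suppressPackageStartupMessages(library(fitvalid))

coh <- read_cohort("results/prepared_cohort.csv")
trend <- monthly_trend(coh)
utils::write.csv(trend, "results/monthly_positivity.csv", row.names = FALSE)

reg <- volume_positivity_regression(trend, c("2020-07", "2023-06"))
cat(sprintf("Volume vs positivity (2020-07..2023-06): R^2 = %.2f, slope p = %.3g over %d months\n",
            reg$r_squared, reg$p_slope, reg$n_months))

crc <- coh$crc == 1
sex_chi <- pearson_chi2_2x2(sum(!crc & coh$sex == "male"),
                            sum(crc & coh$sex == "male"),
                            sum(!crc & coh$sex != "male"),
                            sum(crc & coh$sex != "male"))
fit_chi <- pearson_chi2_2x2(sum(!crc & coh$fit_value >= 10),
                            sum(crc & coh$fit_value >= 10),
                            sum(!crc & coh$fit_value < 10),
                            sum(crc & coh$fit_value < 10))
age_u <- mann_whitney_u(coh$age[!crc], coh$age[crc])
desc <- data.frame(
  comparison = c("male sex by cancer", "FIT >= 10 by cancer",
                 "age by cancer (U)"),
  statistic = c(sex_chi$statistic, fit_chi$statistic, age_u$U),
  p_value = c(sex_chi$p_value, fit_chi$p_value, NA))
utils::write.csv(desc, "results/descriptive_tests.csv", row.names = FALSE)

print(desc)
cat(sprintf("Median age: cancers %.1f vs non-cancers %.1f\n",
            age_u$median1, age_u$median0))
cat("Wrote results/monthly_positivity.csv and results/descriptive_tests.csv\n")
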