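#!/usr/bin/env Rscript

# Validate the claims bundle, build the analytic cohort (index dates,
# eligibility, initiation months, baseline covariates, costs, exacerbation
# episodes) and write the cohort tables under results/.
#
# Usage: Rscript analysis/02_build_cohort.R   (after 01_simulate.R)

library(msmdelay)

config <- read_config("results/config.yaml")
bundle <- read_bundle("results/claims", config)
validation_report(bundle)

parts <- build_cohort(bundle, config)

cat("\nattrition:\n")
print(parts$attrition)
cat("\ninitiation-month distribution:\n")
print(table(parts$cohort$initiation_month))

dir.create("results", showWarnings = FALSE)
data.table::fwrite(parts$cohort, "results/cohort.csv")
data.table::fwrite(parts$attrition, "results/attrition.csv")
data.table::fwrite(parts$episodes, "results/episodes.csv")
data.table::fwrite(parts$monthly, "results/monthly_indicators.csv")
cat("\nwrote results/cohort.csv, attrition.csv, episodes.csv, monthly_indicators.csv\n")
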