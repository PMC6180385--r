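#!/usr/bin/env Rscript

# Expand the cohort into a person-month panel, fit the pooled monthly
# treatment-selection models, and compute stabilized truncated weights.
#
# Usage: Rscript analysis/03_weights.R   (after 02_build_cohort.R)

library(msmdelay)

config <- read_config("results/config.yaml")
bundle <- read_bundle("results/claims", config)
parts <- build_cohort(bundle, config)

panel <- expand_person_months(parts$cohort, parts$episodes, bundle, config)
models <- fit_treatment_models(panel, config)

cat("denominator selection model (time-varying covariates):\n")
print(summary(models$denominator)$coefficients[
  c("exac_prev", "rescue_prev", "infection_prev"), , drop = FALSE])

swpanel <- compute_stabilized_weights(panel, models)
cat("\nweight diagnostics (person-month stabilized weights):\n")
print(weight_diagnostics(swpanel$sw, config$truncation_percentile))

subj_w <- subject_weights(swpanel, config)
data.table::fwrite(swpanel, "results/panel_weights.csv")
data.table::fwrite(subj_w, "results/subject_weights.csv")
cat("\nwrote results/panel_weights.csv, results/subject_weights.csv\n")
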