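#!/usr/bin/env Rscript

# Generate the synthetic claims bundle used by the downstream analysis scripts
# and write it (plus the generator's truth ledger) under results/.
#
# Usage: Rscript analysis/01_simulate.R [seed] [n_patients]

library(msmdelay)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260401L
n <- if (length(args) >= 2) as.integer(args[2]) else 2200L

config <- study_config()
truth <- ground_truth(n_patients = n, seed = seed)
print(truth)

gen <- generate_bundle(truth, config)
print(gen$bundle)

dir.create("results/claims", showWarnings = FALSE, recursive = TRUE)
write_bundle(gen$bundle, "results/claims")
data.table::fwrite(gen$ledger, "results/truth_ledger.csv")
write_config(config, "results/config.yaml")

cat("\nbaseline margins (all generated patients):\n")
print(summarize_margins(gen$bundle, config))
cat("\nwrote results/claims/{enrollment,medical,pharmacy}.csv,",
    "results/truth_ledger.csv, results/config.yaml\n")
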