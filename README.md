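# msmdelay

Marginal structural models for the cost and severe-exacerbation consequences of
**delaying initiation** of a COPD maintenance therapy (umeclidinium/vilanterol,
UMEC/VI), estimated from administrative claims.

## The problem

In a new-user cohort of COPD patients who all start maintenance therapy within
12 months of their index diagnosis visit, how much do 12-month medical costs
and the monthly hazard of a first severe exacerbation depend on *when* therapy
starts? Initiation timing is confounded by time-varying disease severity:
patients doing badly initiate sooner **and** cost more, so naive regressions
understate the harm of delay. The package implements the standard g-method
answer — inverse-probability-of-treatment weighting:

* **Stabilized weights** from two pooled monthly logistic treatment-selection
  models over at-risk person-months (numerator: baseline covariates + month
  terms; denominator: + lagged time-varying covariates — prior-month
  exacerbation, rescue-inhaler fill, respiratory-infection visit), cumulated
  up to initiation, frozen afterwards, truncated at the 99.9th percentile.
* **Outcome models** as weighted GEEs with cluster-robust (Liang–Zeger)
  variances: a gamma/log-link model of 12-month COPD-related and all-cause
  cost, one row per subject, `exp(β_month)` = per-month cost ratio of delay;
  and a discrete-time first-severe-exacerbation model (person-month logit with
  an `untreated` flag and optionally its interaction with centered month),
  whose exponentiated coefficients approximate hazard ratios.

Supporting machinery, all tested: a claims-bundle reader/validator, a new-user
cohort builder (index dates, eligibility with attrition, 30-day month grid,
baseline covariates including a configurable Charlson score, cost
aggregation), the claims-based exacerbation-episode algorithm (severe =
inpatient COPD claim; moderate = COPD outpatient visit + corticosteroid/
antibiotic fill within 5 days; 14-day chain merge, highest severity wins), a
weighted GEE solver (`wgee()`, independence/exchangeable, cross-checked
against `glm` + `sandwich::vcovCL`), and a **seeded synthetic-claims
generator** with a known confounding structure used to validate the whole
pipeline by parameter recovery. See the methods vignette
(`vignettes/msm-delayed-initiation.Rmd`) for the model, the generator design,
and the design decisions.

## Worked example

Generate a synthetic population with planted effects (per-month COPD cost
ratio 1.029, untreated severe-exacerbation OR 1.74, per-month interaction
1.08, confounding on), run the full pipeline, and compare the weighted and
unweighted answers:

```r
library(msmdelay)

config <- study_config()
gen <- generate_bundle(ground_truth(n_patients = 2200L, seed = 1L), config)
res <- run_msm_pipeline(gen$bundle, config, naive = TRUE, report = TRUE)

print(res$report)
```

```
<effect_report>
  COPD-related cost: +2.4% per month of delay; Month 12 vs 1: $15,089 vs $11,633 (+29.7%)
  all-cause cost:    +2.9% per month of delay; Month 12 vs 1: $27,018 vs $19,776 (+36.6%)
  untreated severe-exacerbation HR 1.88 (1.47-2.40), per-month interaction 1.05 (0.99-1.13)
  HR without interaction: 1.67 (1.38-2.01)
```

```r
# time-varying confounding in action: the unweighted per-month % is biased low
per_month_pct_change(res$naive_cost_copd)
per_month_pct_change(res$fit_cost_copd)
```

```
      pct        lo        hi 
1.5126476 0.3843594 2.6536175 
     pct       lo       hi 
2.392586 1.063684 3.738963 
```

```r
weight_diagnostics(res$swpanel$sw, config$truncation_percentile)
```

```
       n      mean        sd       min      max      cap pct_capped
   <int>     <num>     <num>     <num>    <num>    <num>      <num>
1: 26400 0.9972354 0.3799982 0.1691922 6.947636 3.711275 0.09469697
```

`render_report(res$report, "results")` writes `results/report.json` and
`results/report.txt` (byte-stable for a fixed seed and configuration).

## Analysis scripts

The numbered scripts under `analysis/` run the same pipeline stepwise, writing
intermediate tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # claims bundle + truth ledger + config
Rscript analysis/02_build_cohort.R        # cohort, attrition, episodes
Rscript analysis/03_weights.R             # panel, selection models, weights
Rscript analysis/04_fit_models.R          # outcome models + effect report
Rscript analysis/05_recovery.R 20 2000    # replicated parameter recovery
```

## Package layout

```
R/                  package source (claims_io, synthetic_claims, cohort_builder,
                    exacerbation_episodes, msm_weights, outcome_models,
                    effects_report, validation)
analysis/           numbered analysis drivers (thin wrappers over the package)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (source)
```
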