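---
title: "Methods: marginal structural models for delayed COPD maintenance-therapy initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marginal structural models for delayed COPD maintenance-therapy initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the design decisions, and the
synthetic-claims generator behind `msmdelay`. The package estimates the effect
of *delaying* initiation of a COPD maintenance therapy (umeclidinium/vilanterol,
UMEC/VI) on 12-month medical costs and on the monthly hazard of a first severe
exacerbation, from administrative claims, in a new-user cohort where everyone
eventually initiates within the first year after diagnosis.

## 1. The causal problem

Patients who are doing badly (more exacerbations, more rescue-inhaler use,
respiratory infections) are *more* likely to start maintenance therapy soon
**and** more likely to have high costs and severe exacerbations. Month of
initiation is therefore confounded by time-varying disease severity that is
itself affected by earlier treatment decisions. A standard regression that
conditions on post-baseline severity blocks part of the treatment effect; one
that omits it is confounded. Marginal structural models (MSMs) solve this by
*reweighting*: each person-month is weighted by the inverse probability of the
treatment status actually observed, so that in the weighted pseudo-population
treatment is independent of the measured time-varying confounders.

## 2. Study design

* **Index date**: first COPD-related medical claim from an eligible prescriber
  specialty on or after the plan-specific formulary-availability date of the
  therapy, and no later than the index-assignment cutoff.
* **Eligibility**: age ≥ 40 in the index year; at least one UMEC/VI fill inside
  the identification period *and* inside the 12-month follow-up; continuous
  enrollment from formulary availability through index, the 6-month baseline,
  and the 12-month follow-up; no baseline UMEC/VI or other LAMA/LABA
  fixed-dose-combination use.
* **Month grid**: fixed 30-day bins from the index date (day 0). A fill on
  day 0 is Month-1 initiation; day 359 is Month 12. Delay is the
  (reconciled) initiation month, 1–12.
* **Reconciliation**: if the patient's earliest exacerbation episode in the
  initiation month starts strictly before the first fill, initiation is
  attributed to the next month, so that the exacerbation counts as untreated
  exposure time. Ties on the same day do not move the month; a bump beyond
  Month 12 is capped there and counted.

Attrition is recorded criterion by criterion and is monotone by construction
(`apply_eligibility()`).

## 3. Exacerbation episodes from claims

A **severe** event is an inpatient claim with a COPD diagnosis in any position.
A **moderate** event is a COPD-related ED / office / urgent-care visit with a
systemic or oral corticosteroid or COPD-recommended antibiotic fill within 5
days *on or after* the visit (treatment follows the visit; earlier fills never
qualify). Events within 14 days of each other chain-merge into one episode
(`merge_episodes()`), classified by the highest contributing severity. Both
windows are inclusive; the chain rule is transitive, so an episode can span
more than 14 days in total. The merge is order-invariant and is tested against
a brute-force transitive-closure oracle.

## 4. Weights

For each month `t` up to and including initiation, two pooled logistic
regressions model the initiation hazard over at-risk person-months:

* numerator: baseline covariates `V` plus flexible month terms (categorical by
  default);
* denominator: the same plus lagged time-varying covariates `L_t`
  (prior-month exacerbation episode, rescue-medication fill, respiratory
  infection visit; month 1 uses the last baseline month).

The stabilized weight is the running product of numerator/denominator
likelihood contributions of the *observed* status (`p` in the initiation month,
`1 − p` before), frozen after initiation (treatment is absorbing and everyone
stays enrolled, so there are no censoring weights). Weights are truncated at
the 99.9th percentile — the conventional compromise between bias and variance
of weighted estimators; the percentile is the standard linear-interpolation
order-statistic estimate (R's default type-7 quantile) and is configurable.

## 5. Outcome models

* **Costs**: 12-month COPD-related and all-cause costs, one row per subject,
  gamma distribution with log link, linear in initiation month and `V`,
  weighted by the subject's truncated weight at initiation, independence
  working correlation, robust (sandwich) SEs. `exp(β_month)` is the per-month
  cost ratio of delay; "adjusted" Month-`m` costs are weighted marginal
  standardizations over the cohort, so adjusted(12)/adjusted(1) is identically
  `exp(11·β_month)` — an identity the tests check.
* **Severe exacerbation**: a discrete-time first-event (person-period) model.
  Subjects contribute one row per month until their first severe episode
  month; the event logit is modelled on an `untreated` indicator, optionally
  its interaction with month centered at Month 6, and `V`, with monthly
  truncated stabilized weights and robust SEs clustered on subject
  (exchangeable working correlation by default). Exponentiated coefficients
  approximate hazard ratios because monthly risks are small.

No GEE solver is among the package's dependencies, so `wgee()` implements the
weighted estimating equations directly: Fisher scoring, independence or
exchangeable working correlation with a moment estimator for the exchangeable
correlation, and the Liang–Zeger sandwich. For the independence case the tests
cross-check coefficients and robust covariance against an independent oracle,
`stats::glm()` plus `sandwich::vcovCL()`; the exchangeable case is checked to
collapse to independence on singleton clusters and to recover a known
intra-cluster correlation on simulated clustered data.

## 6. The synthetic-claims generator

Claims data of the kind this analysis needs cannot be redistributed, so the
package ships a seeded generator (`generate_bundle()`) that emits the three
claims tables for a population with a *known* time-varying confounding
structure, plus a "truth ledger" of every latent quantity. The generator is
first-class, tested code: it is how the pipeline is validated.

Per patient:

1. **Baseline covariates** match the margins of the target population: age
   69.3 (SD 9.9, truncated to 40–95), 49.9% female, 69.7% Medicare Advantage,
   Charlson score ≈ 1.5 on average (planted via a carrier claim whose
   diagnosis codes greedily decompose the target score), baseline
   moderate/severe exacerbation counts (0.6/0.1 per 6 months), medication-class
   shares, 25% emphysema.
2. **Latent severity** `S_t` is a stationary two-state Markov chain
   (prevalence 0.30, persistence 0.75), independent of baseline covariates and
   *never affected by treatment* — so the planted treatment effects below are
   exactly the marginal estimands.
3. **Initiation**: monthly logistic hazard in baseline covariates, a month
   profile, and `S_{t−1}` scaled by the confounding knob (default 1.2).
   Trajectories that never initiate within 12 months are redrawn, mirroring
   the cohort's conditioning on initiation.
4. **Events**: monthly severe-event logit with planted untreated log-OR
   `log(1.74)` and centered-month interaction `log(1.08)`, plus a severity
   effect of 0.35; moderate events follow a severity-linked hazard.
5. **Costs**: gamma totals (shape 1.5) with log-mean linear in covariates,
   mean follow-up severity, and `log(1.029)` per month of delay for
   COPD-related cost; the non-COPD delay slope is *derived* so the implied
   all-cause per-month ratio is exactly 1.028.

Severity leaves an exact claims footprint: a rescue-inhaler fill mid-month
whenever `S_t = 1`, so the pipeline's lagged rescue covariate *equals* the true
confounder and the fitted selection model is correctly specified. Initiation
fills sit at bin starts and events strictly inside bins, so initiation months,
costs (to the cent), and first-severe months are reconstructible exactly —
each of these reconstructions is a test.

**Deliberate design choices and what the generator does *not* emulate**

* The severe-event effect is placed mostly on the *initiation* side
  (confounding 1.2) and kept moderate on the outcome side (0.35) in a
  rare-event regime (~1–3% monthly risk), so the marginal odds ratios differ
  negligibly from the planted conditional ones (non-collapsibility is a
  real-data headache this generator intentionally sidesteps).
* The initiation-hazard profile rises over months 7–12. Because the cohort
  conditions on initiation within 12 months, a flat profile would leave ~16%
  of trajectories never initiating, and that informative selection biases
  *even the correctly weighted estimator*. With the rising profile the redraw
  rate is ~3% and the selection bias is negligible. The price is that the
  conditional initiation-timing distribution (~25% in Month 1, ~71% by
  Month 6) is only an approximation of a realistic one; matching a realistic
  timing distribution exactly while keeping never-initiators rare would force
  a degenerate Month-12 hazard.
* No death, disenrollment, plan switching, coding error, duplicate claims, or
  seasonality; costs are already in constant dollars (the deflator hook is a
  pass-through); medication classes are labels, not NDC codes; diagnosis
  coding uses a handful of representative codes rather than full ICD lists.

Default problem sizes (2,200 patients in the analysis scripts, 5,000 for the
single-run recovery check, 200 replicates of 2,000 for coverage) are the
package's own choices, sized so the full test suite runs on one CPU in
minutes.

## 7. Validation strategy

* **Exact oracles**: hand-computed stabilized weights on a 2-patient toy;
  weight cancellation with identical numerator/denominator models; truncation
  against a direct percentile computation; episode merging against transitive
  closure; wgee against `glm` + `vcovCL`; the standardization and
  hazard-ratio identities.
* **Worked examples**: the published adjusted costs imply per-month changes of
  2.9%/2.8% and relative differences of 37.4%/36.1%; the reporting layer's
  transforms reproduce these from the printed numbers alone.
* **Parameter recovery**: the full pipeline on generated claims recovers the
  planted per-month cost ratio and both hazard-ratio parameters within
  sampling error at n = 5,000, with ≥ 90% CI coverage over 200 replicates at
  n = 2,000, while the unweighted estimator stays biased (≥ 3× the weighted
  bias on the confounded parameters).

## 8. Reproducing an analysis

```{r pipeline}
library(msmdelay)
config <- study_config()
gen <- generate_bundle(ground_truth(n_patients = 2200L, seed = 1L), config)
res <- run_msm_pipeline(gen$bundle, config, naive = TRUE, report = TRUE)
print(res$report)
render_report(res$report, "results")
```

The numbered scripts under `analysis/` run the same pipeline stepwise
(simulate → cohort → weights → models → recovery) and write intermediate
tables under `results/`; `scripts/acceptance.R` runs everything once at
n = 5,000 and writes the headline quantities as JSON.

## 9. Limitations

* Hazard ratios come from a discrete-time logit model; the HR interpretation
  leans on monthly risks being small.
* Robust sandwich variances ignore the estimation of the weights themselves;
  this is the standard practice and is typically conservative.
* The weighting covariate set is the generator's truth; on real claims the
  no-unmeasured-confounding assumption is untestable, and the episode
  algorithm's windows (5/14 days) are conventions, not estimates.
* The generator's severity process is exogenous by design; it cannot be used
  to study treatment-confounder feedback in the strict sense (where g-methods
  are the *only* consistent estimators), only time-varying confounding of the
  initiation decision.
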