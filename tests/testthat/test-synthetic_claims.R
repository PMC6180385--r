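cfg <- study_config()

test_that("generation is deterministic given the seed", {
  g1 <- generate_bundle(ground_truth(n_patients = 120L, seed = 9L), cfg)
  g2 <- generate_bundle(ground_truth(n_patients = 120L, seed = 9L), cfg)
  expect_equal(g1$ledger, g2$ledger)
  for (tb in c("enrollment", "medical", "pharmacy")) {
    expect_equal(as.data.frame(g1$bundle[[tb]]), as.data.frame(g2$bundle[[tb]]))
  }
  g3 <- generate_bundle(ground_truth(n_patients = 120L, seed = 10L), cfg)
  expect_false(isTRUE(all.equal(g1$ledger$initiation_month,
                                g3$ledger$initiation_month)))
})

test_that("degenerate parameters raise errors rather than looping", {
  expect_error(ground_truth(n_patients = 0L))
  tr <- ground_truth(n_patients = 50L, seed = 2L)
  tr$init_p_by_month <- rep(1e-8, 12)
  expect_error(generate_bundle(tr, cfg), "never initiate")
})

test_that("the pipeline reconstructs the planted latent quantities exactly", {
  gen <- small_gen()
  parts <- build_cohort(gen$bundle, cfg)
  led <- gen$ledger
  # every generated patient passes eligibility
  expect_equal(nrow(parts$cohort), nrow(led))
  m <- merge(parts$cohort, led, by = "patient_id", suffixes = c("", ".led"))
  expect_equal(nrow(m), nrow(led))
  # initiation month from claims equals the planted month (no reconciliation
  # bumps: fills are at bin starts, events strictly inside the bin)
  expect_equal(m$initiation_month, m$initiation_month.led)
  expect_equal(m$initiation_month_raw, m$initiation_month.led)
  # 12-month COPD cost equals the drawn total to the cent
  expect_equal(m$copd_cost_12m, m$copd_cost_12m.led, tolerance = 1e-9)
  expect_equal(m$allcause_cost_12m, m$copd_cost_12m.led + m$noncopd_cost_12m,
               tolerance = 1e-9)
  # first severe episode month equals first severe event month (moderate events
  # that would chain-merge into a severe event are suppressed at generation)
  fs <- merge(parts$first_severe, led[, c("patient_id", "first_severe_month")],
              by = "patient_id", suffixes = c("", ".led"), all = TRUE)
  expect_equal(fs$first_severe_month, fs$first_severe_month.led)
  # measured Charlson and baseline covariates match the planted ones
  expect_equal(m$charlson, m$charlson_obs)
  expect_equal(m$age.led, m$age)
  expect_equal(m$base_sev_exac + m$base_mod_exac, m$base_mod + m$base_sev)
})

test_that("the lagged rescue covariate recovers the latent severity path", {
  gen <- small_gen()
  parts <- build_cohort(gen$bundle, cfg)
  panel <- expand_person_months(parts$cohort, parts$episodes, gen$bundle, cfg)
  led <- gen$ledger
  # severity_path is "S0S1...S12"; rescue_prev for month t should equal S_{t-1}
  truth_lag <- data.table::data.table(
    patient_id = rep(led$patient_id, each = 12L),
    month = rep(1:12, nrow(led)),
    s_lag = as.integer(unlist(lapply(led$severity_path,
                                     function(s) strsplit(s, "")[[1]][1:12]))))
  chk <- merge(panel[, .(patient_id, month, rescue_prev)], truth_lag,
               by = c("patient_id", "month"))
  expect_equal(chk$rescue_prev, chk$s_lag)
})

test_that("baseline margins approach the configured targets as n grows", {
  gen <- generate_bundle(ground_truth(n_patients = 5000L, seed = 77L), cfg)
  marg <- summarize_margins(gen$bundle, cfg)
  tr <- ground_truth()
  expect_equal(marg$n, 5000L)
  expect_lt(abs(marg$age_mean - tr$age_mean), 0.4)
  expect_lt(abs(marg$age_sd - tr$age_sd), 0.4)
  expect_lt(abs(marg$pct_female - 100 * tr$pct_female), 2)
  expect_lt(abs(marg$pct_mapd - 100 * tr$pct_mapd), 2)
  # Charlson: extra score ~NB(1.35) floored at 1 when there are baseline
  # exacerbations; the claims-measured mean should land near 1.5
  expect_lt(abs(marg$charlson_mean - 1.5), 0.15)
  expect_lt(abs(marg$base_exac_mean - (tr$base_mod_rate + tr$base_sev_rate)), 0.1)
})

test_that("the confounding knob is recovered by the selection model", {
  ks <- c(0, 1.2, 2.4)
  fitted_k <- vapply(ks, function(k) {
    tr <- ground_truth(n_patients = 1500L, confounding_strength = k, seed = 505L)
    gen <- generate_bundle(tr, cfg)
    parts <- build_cohort(gen$bundle, cfg)
    panel <- expand_person_months(parts$cohort, parts$episodes, gen$bundle, cfg)
    models <- fit_treatment_models(panel, cfg)
    coef(models$denominator)[["rescue_prev"]]
  }, numeric(1))
  # the lagged rescue covariate equals the latent severity state, whose planted
  # log-odds effect on initiation is exactly the knob
  expect_lt(max(abs(fitted_k - ks)), 0.3)
  expect_true(all(diff(fitted_k) > 0.5))
})

test_that("with confounding off the unweighted estimate recovers the truth", {
  tr <- ground_truth(n_patients = 1500L, confounding_strength = 0, seed = 505L)
  gen <- generate_bundle(tr, cfg)
  parts <- build_cohort(gen$bundle, cfg)
  fit <- fit_cost_model(parts$cohort, rep(1, nrow(parts$cohort)), "copd", cfg)
  tab <- wgee_table(fit)[term == "initiation_month"]
  expect_lt(abs(tab$estimate - tr$beta_delay_cost), 3 * tab$se_robust)
})

test_that("derived non-COPD delay slope reproduces the all-cause ratio", {
  tr <- ground_truth()
  bnc <- msmdelay:::derive_noncopd_delay(tr, cfg)
  A <- exp(tr$mu0_copd); B <- exp(tr$mu0_noncopd)
  implied <- ((A * exp(11 * tr$beta_delay_cost) + B * exp(11 * bnc)) /
                (A + B))^(1 / 11)
  expect_equal(implied, tr$allcause_ratio, tolerance = 1e-12)
})
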