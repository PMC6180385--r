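cfg <- study_config()

test_that("independence wgee equals the weighted GLM + vcovCL oracle (gamma)", {
  pipe <- small_pipeline()
  fit <- pipe$fit_cost_copd
  co <- data.table::copy(pipe$cohort)
  co <- pipe$subject_weights[, .(patient_id, w = sw_trunc)][co, on = "patient_id"]
  f <- stats::as.formula(paste("copd_cost_12m ~ initiation_month +",
                               paste(baseline_covariate_names(cfg), collapse = " + ")))
  oracle <- stats::glm(f, data = co, weights = co$w,
                       family = stats::Gamma(link = "log"),
                       control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  expect_equal(coef(fit), coef(oracle), tolerance = 1e-6)
  Vo <- sandwich::vcovCL(oracle, cluster = co$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov_robust), unname(Vo), tolerance = 1e-5)
})

test_that("independence wgee equals the weighted GLM + vcovCL oracle (logit)", {
  pipe <- small_pipeline()
  fit <- fit_exacerbation_model(pipe$swpanel, cfg, include_interaction = TRUE,
                                corstr = "independence")
  pm <- data.table::copy(pipe$swpanel)
  pm <- pm[is.na(first_severe_month) | month <= first_severe_month]
  pm[, event := as.integer(!is.na(first_severe_month) & month == first_severe_month)]
  pm[, untreated := 1L - treated]
  pm[, untreated_cmonth := untreated * (month - cfg$interaction_center_month)]
  pm[, w := as.numeric(truncate_weights(sw, cfg$truncation_percentile))]
  f <- stats::as.formula(paste("event ~ untreated + untreated_cmonth +",
                               paste(baseline_covariate_names(cfg), collapse = " + ")))
  oracle <- stats::glm(f, data = pm, weights = pm$w,
                       family = stats::quasibinomial(),
                       control = stats::glm.control(epsilon = 1e-12, maxit = 200))
  expect_equal(coef(fit), coef(oracle), tolerance = 1e-6)
  Vo <- sandwich::vcovCL(oracle, cluster = pm$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov_robust), unname(Vo), tolerance = 1e-5)
})

test_that("exchangeable wgee on singleton clusters equals independence", {
  pipe <- small_pipeline()
  co <- data.table::copy(pipe$cohort)
  co[, w := 1]
  f <- copd_cost_12m ~ initiation_month + age + female + charlson
  ind <- wgee(f, co, id = co$patient_id, weights = co$w,
              family = stats::Gamma(link = "log"), corstr = "independence")
  exch <- wgee(f, co, id = co$patient_id, weights = co$w,
               family = stats::Gamma(link = "log"), corstr = "exchangeable")
  expect_equal(coef(exch), coef(ind), tolerance = 1e-9)
  expect_equal(exch$vcov_robust, ind$vcov_robust, tolerance = 1e-9)
})

test_that("exchangeable working correlation is estimated on clustered data", {
  # strongly correlated within-cluster gaussian outcomes
  set.seed(12)
  nclus <- 300L
  u <- rnorm(nclus, sd = 1)
  d <- data.table::data.table(
    id = rep(sprintf("C%03d", seq_len(nclus)), each = 4L),
    x = rnorm(nclus * 4L))
  d[, y := 1 + 0.5 * x + rep(u, each = 4L) + rnorm(.N, sd = 0.5)]
  fit <- wgee(y ~ x, d, id = d$id, family = stats::gaussian(),
              corstr = "exchangeable")
  # true exchangeable correlation = 1 / (1 + 0.25) = 0.8
  expect_lt(abs(fit$alpha - 0.8), 0.05)
  expect_lt(abs(coef(fit)[["x"]] - 0.5), 0.05)
  expect_equal(fit$n_clusters, nclus)
})

test_that("cost model handles zero-cost subjects per configuration", {
  pipe <- small_pipeline()
  co <- data.table::copy(pipe$cohort)
  co[1:3, copd_cost_12m := 0]
  w <- rep(1, nrow(co))
  fit_off <- fit_cost_model(co, w, "copd", cfg)
  expect_equal(attr(fit_off, "n_zero_adjusted"), 3L)
  expect_equal(fit_off$n_obs, nrow(co))
  cfg_drop <- study_config(zero_cost = "drop")
  fit_drop <- fit_cost_model(co, w, "copd", cfg_drop)
  expect_equal(fit_drop$n_obs, nrow(co) - 3L)
  co_zero <- data.table::copy(co)[, copd_cost_12m := 0]
  expect_error(fit_cost_model(co_zero, w, "copd", cfg), "all-zero")
})

test_that("exacerbation model risk sets end at the first severe month", {
  pipe <- small_pipeline()
  pm <- pipe$swpanel
  with_event <- pm[!is.na(first_severe_month)]
  expect_gt(nrow(with_event), 0)
  # panel months after the first severe month are excluded from the fit's rows
  n_expected <- nrow(pm[is.na(first_severe_month)]) +
    sum(unique(with_event, by = "patient_id")$first_severe_month)
  fit <- fit_exacerbation_model(pm, cfg, include_interaction = TRUE,
                                corstr = "independence")
  expect_equal(fit$n_obs, n_expected)
  # no-events panel errors
  none <- data.table::copy(pm)[, first_severe_month := NA_integer_]
  expect_error(fit_exacerbation_model(none, cfg), "no severe exacerbation events")
})

test_that("hazard-ratio arithmetic matches closed forms on stubbed coefficients", {
  fit <- stub_exac_fit(log(1.74), log(1.08))
  # at the centering month the interaction vanishes
  expect_equal(unname(hazard_ratio_at_month(fit, 6L, cfg)[1, "hr"]), 1.74,
               tolerance = 1e-12)
  # one month later multiplies by the interaction ratio
  expect_equal(unname(hazard_ratio_at_month(fit, 7L, cfg)[1, "hr"]), 1.74 * 1.08,
               tolerance = 1e-12)
  expect_equal(unname(hazard_ratio_at_month(fit, 12L, cfg)[1, "hr"]),
               1.74 * 1.08^6, tolerance = 1e-12)
  expect_error(hazard_ratio_at_month(fit, 13L, cfg), "out of range")
  no_int <- stub_exac_fit(log(1.74), log(1.08))
  no_int$coefficients <- no_int$coefficients[c("(Intercept)", "untreated")]
  expect_error(hazard_ratio_at_month(no_int, 6L, cfg), "interaction")
})

test_that("wgee errors on singular designs instead of returning garbage", {
  d <- data.frame(id = rep(1:20, each = 2), y = rnorm(40), x = 1)
  d$x2 <- d$x
  expect_error(wgee(y ~ x + x2, d, id = d$id), "singular")
})
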