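cfg <- study_config()

test_that("toy cohort applies index, eligibility and initiation-month rules", {
  b <- toy_bundle()
  idx <- assign_index_date(b, cfg)
  expect_setequal(idx$patient_id, c("P1", "P2", "P3"))
  expect_true(all(idx$index_date == as.Date("2015-03-01")))
  elig <- apply_eligibility(b, idx, cfg)
  expect_equal(elig$records$patient_id, "P1")  # P2 under age, P3 baseline FDC
  at <- elig$attrition
  expect_equal(at$n[1], 3L)
  expect_true(!is.unsorted(rev(at$n)))
  expect_equal(at[grepl("age", at$criterion)]$n, 2L)
  rec <- assign_initiation_month(elig$records, b, cfg)
  expect_equal(rec$initiation_month, 2L)  # fill on day 35
  expect_equal(rec$first_fill_date, as.Date("2015-04-05"))
})

test_that("index dates respect specialty, formulary start and the window end", {
  enrollment <- data.frame(
    patient_id = c("A", "B", "C"),
    plan_type = c("medicare_advantage", "commercial", "commercial"),
    coverage_start = "2013-01-01", coverage_end = "2016-12-31",
    birth_year = 1950L, sex = "female")
  medical <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    service_date = c("2014-06-01",  # before MAPD formulary start (2015-01-01)
                     "2015-02-01",  # first qualifying for A
                     "2015-10-15",  # after index_assignment_end
                     "2015-05-01"),
    dx_codes = "4919",
    place = "office",
    provider_specialty = c("gp", "gp", "gp", "chiropractic"),
    paid_total = 0)
  pharmacy <- data.frame(patient_id = "A", fill_date = "2015-02-01",
                         drug_class = "umec_vi", paid_total = 300)
  idx <- assign_index_date(claims_bundle(enrollment, medical, pharmacy), cfg)
  expect_equal(idx$patient_id, "A")
  expect_equal(idx$index_date, as.Date("2015-02-01"))
  expect_equal(idx$plan_type, "medicare_advantage")
})

test_that("initiation-month bins are half-open 30-day bins from day 0", {
  mk <- function(offset) {
    enrollment <- data.frame(patient_id = "A", plan_type = "commercial",
                             coverage_start = "2013-01-01",
                             coverage_end = "2016-12-31",
                             birth_year = 1950L, sex = "female")
    medical <- data.frame(patient_id = "A", service_date = "2015-01-15",
                          dx_codes = "4919", place = "office",
                          provider_specialty = "gp", paid_total = 0)
    pharmacy <- data.frame(patient_id = "A",
                           fill_date = format(as.Date("2015-01-15") + offset),
                           drug_class = "umec_vi", paid_total = 300)
    b <- claims_bundle(enrollment, medical, pharmacy)
    rec <- data.table::data.table(patient_id = "A",
                                  index_date = as.Date("2015-01-15"),
                                  plan_type = "commercial",
                                  birth_year = 1950L, sex = "female")
    assign_initiation_month(rec, b, cfg)$initiation_month
  }
  expect_equal(mk(0L), 1L)    # fill on the index date
  expect_equal(mk(29L), 1L)
  expect_equal(mk(30L), 2L)
  expect_equal(mk(359L), 12L) # last follow-up day
})

test_that("cost aggregation windows, COPD restriction and deflator", {
  enrollment <- data.frame(patient_id = "A", plan_type = "commercial",
                           coverage_start = "2013-01-01", coverage_end = "2016-12-31",
                           birth_year = 1950L, sex = "female")
  idxd <- as.Date("2015-01-15")
  medical <- data.frame(
    patient_id = "A",
    service_date = format(idxd + c(-1L, 0L, 100L, 359L, 360L)),
    dx_codes = c("4919", "4919", "2500", "J449", "4919"),
    place = "other", provider_specialty = "lab",
    paid_total = c(1000, 100, 50, 200, 5000))
  pharmacy <- data.frame(patient_id = "A", fill_date = "2015-01-15",
                         drug_class = "umec_vi", paid_total = 300)
  b <- claims_bundle(enrollment, medical, pharmacy)
  rec <- data.table::data.table(patient_id = "A", index_date = idxd)
  out <- aggregate_costs(rec, b, cfg)
  # day -1 and day 360 excluded; COPD = 100 + 200, all-cause adds the 50
  expect_equal(out$copd_cost_12m, 300)
  expect_equal(out$allcause_cost_12m, 350)
  expect_true(out$copd_cost_12m <= out$allcause_cost_12m)
  # deflator applies per claim calendar year: the day-359 claim falls in 2016
  # and is left unscaled by a 2015-only deflator
  defl <- aggregate_costs(rec, b, cfg, deflator = c("2015" = 2))
  expect_equal(defl$allcause_cost_12m, 2 * (100 + 50) + 200)
  defl2 <- aggregate_costs(rec, b, cfg, deflator = c("2015" = 2, "2016" = 2))
  expect_equal(defl2$allcause_cost_12m, 700)
  expect_equal(defl2$copd_cost_12m, 600)
})

test_that("baseline covariates measure the six-month pre-index window", {
  enrollment <- data.frame(patient_id = "A", plan_type = "medicare_advantage",
                           coverage_start = "2013-01-01", coverage_end = "2016-12-31",
                           birth_year = 1950L, sex = "female")
  idxd <- as.Date("2015-06-01")
  medical <- data.frame(
    patient_id = "A",
    service_date = format(c(idxd - 100L,  # baseline: inpatient COPD (severe)
                            idxd - 50L,   # baseline: diabetes + CHF dx
                            idxd - 200L,  # before baseline window
                            idxd)),       # emphysema at index
    dx_codes = c("4919", "2500;428", "196", "4928"),
    place = c("inpatient", "other", "other", "office"),
    provider_specialty = c("hosp", "lab", "lab", "gp"),
    paid_total = 10)
  pharmacy <- data.frame(
    patient_id = "A",
    fill_date = format(c(idxd - 30L, idxd - 10L, idxd - 181L)),
    drug_class = c("ics", "saba", "lama"),  # lama fill is outside baseline
    paid_total = 10)
  b <- claims_bundle(enrollment, medical, pharmacy)
  rec <- data.table::data.table(patient_id = "A", index_date = idxd,
                                plan_type = "medicare_advantage",
                                birth_year = 1950L, sex = "female")
  out <- measure_baseline(rec, b, cfg)
  expect_equal(out$age, 65L)
  expect_equal(out$female, 1L)
  expect_equal(out$mapd, 1L)
  # Charlson: chronic pulmonary (1) + diabetes (1) + CHF (1); the metastatic
  # claim is outside the baseline window
  expect_equal(out$charlson, 3L)
  expect_equal(out$base_sev_exac, 1L)
  expect_equal(out$base_mod_exac, 0L)
  expect_equal(out$base_ics, 1L)
  expect_equal(out$base_saba, 1L)
  expect_equal(out$base_lama, 0L)
  expect_equal(out$emphysema, 1L)  # emphysema window includes the index date
})

test_that("build_cohort output is invariant to claim row order", {
  gen <- generate_bundle(ground_truth(n_patients = 150L, seed = 21L), cfg)
  parts1 <- build_cohort(gen$bundle, cfg)
  b2 <- gen$bundle
  set.seed(1)
  b2$medical <- b2$medical[sample(nrow(b2$medical))]
  b2$pharmacy <- b2$pharmacy[sample(nrow(b2$pharmacy))]
  b2$enrollment <- b2$enrollment[sample(nrow(b2$enrollment))]
  parts2 <- build_cohort(b2, cfg)
  key <- function(x) data.table::setorder(data.table::as.data.table(x), patient_id)
  expect_equal(key(parts2$cohort), key(parts1$cohort))
  expect_equal(parts2$episodes, parts1$episodes)
  expect_equal(parts2$attrition, parts1$attrition)
})

test_that("same-month reconciliation is applied inside build_cohort", {
  # one patient: index 2015-01-15, moderate exacerbation day 32, first therapy
  # fill day 40 (month 2): initiation must move to month 3
  enrollment <- data.frame(patient_id = "A", plan_type = "commercial",
                           coverage_start = "2013-01-01", coverage_end = "2016-12-31",
                           birth_year = 1950L, sex = "female")
  idxd <- as.Date("2015-01-15")
  medical <- data.frame(
    patient_id = "A",
    service_date = format(c(idxd, idxd + 32L)),
    dx_codes = "4919",
    place = c("office", "ed"),
    provider_specialty = c("gp", "em"),
    paid_total = 10)
  pharmacy <- data.frame(
    patient_id = "A",
    fill_date = format(c(idxd + 33L, idxd + 40L)),
    drug_class = c("ocs_systemic_cs", "umec_vi"),
    paid_total = c(10, 300))
  b <- claims_bundle(enrollment, medical, pharmacy)
  parts <- build_cohort(b, cfg)
  expect_equal(parts$cohort$initiation_month_raw, 2L)
  expect_equal(parts$cohort$initiation_month, 3L)
})
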