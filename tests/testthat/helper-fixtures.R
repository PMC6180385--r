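# Shared fixtures and independent oracle implementations for the test suite.

library(data.table)

# ---- small hand-built claims bundle -----------------------------------------
# Three patients around a 2015-03-01 index visit; P1 is fully eligible with a
# month-2 initiation fill, P2 is under age, P3 has a baseline LAMA/LABA FDC.
toy_bundle <- function() {
  enrollment <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    plan_type = c("commercial", "commercial", "medicare_advantage"),
    coverage_start = c("2013-06-01", "2013-06-01", "2013-06-01"),
    coverage_end = c("2016-12-31", "2016-12-31", "2016-12-31"),
    birth_year = c(1950L, 1990L, 1945L),
    sex = c("female", "male", "male"))
  medical <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    service_date = c("2015-03-01", "2015-03-01", "2015-03-01"),
    dx_codes = c("4919", "4919", "J449"),
    place = "office",
    provider_specialty = "gp",
    paid_total = 120)
  pharmacy <- data.frame(
    patient_id = c("P1", "P2", "P3", "P3"),
    fill_date = c("2015-04-05", "2015-03-02", "2015-03-02", "2015-01-15"),
    drug_class = c("umec_vi", "umec_vi", "umec_vi", "lama_laba_fdc"),
    paid_total = 300)
  claims_bundle(enrollment, medical, pharmacy)
}

# ---- deterministic small synthetic bundle for model-level tests -------------
# Cached per session so several test files can share one generation + pipeline.
small_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_bundle(ground_truth(n_patients = 600L, seed = 11L),
                                study_config())
    }
    cache
  }
})

small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_msm_pipeline(small_gen()$bundle, study_config(),
                                 naive = FALSE, report = TRUE)
    }
    cache
  }
})

# ---- independent episode-clustering oracle ----------------------------------
# Transitive closure via union-find on the pairwise "within gap days" relation
# (deliberately a different algorithm from the package's sorted chain merge).
oracle_episodes <- function(dates, severities, gap) {
  n <- length(dates)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(as.integer(dates[i] - dates[j])) <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- data.table(date = dates, severity = severities, root = root)
  out <- out[, .(start_date = min(date), end_date = max(date),
                 severity = if (any(severity == "severe")) "severe" else "moderate",
                 n_events = .N), by = root][, root := NULL]
  setorder(out, start_date)
  out[]
}

# ---- independent type-7 quantile (for the truncation oracle) ----------------
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# ---- constant-probability stub models for weight hand-checks ----------------
# compute_stabilized_weights() only calls predict(model, newdata, type =
# "response"); these stubs return a fixed vector regardless of newdata.
const_prob_model <- function(p) structure(list(p = p), class = "const_prob")

with_const_prob_predict <- function(code) {
  assign("predict.const_prob",
         function(object, newdata, type = "response", ...) {
           rep_len(object$p, nrow(newdata))
         },
         envir = globalenv())
  on.exit(rm("predict.const_prob", envir = globalenv()), add = TRUE)
  force(code)
}

# ---- stub exacerbation fit with chosen coefficients -------------------------
# A minimal object honoring the wgee coef/vcov contract, for arithmetic checks
# on hazard-ratio transforms without a model fit.
stub_exac_fit <- function(b_untreated, b_interaction, se = c(0.1, 0.02)) {
  cf <- c("(Intercept)" = -4, untreated = b_untreated,
          untreated_cmonth = b_interaction)
  V <- diag(c(0.01, se[1]^2, se[2]^2))
  dimnames(V) <- list(names(cf), names(cf))
  structure(list(coefficients = cf, vcov_robust = V,
                 family = stats::binomial(), corstr = "exchangeable",
                 alpha = 0, phi = 1, n_obs = 0L, n_clusters = 0L,
                 label = "stub"), class = "wgee")
}
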