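# Seeded synthetic claims with a known time-varying confounding structure.
#
# Data-generating model (per patient):
#   * Baseline covariates drawn to match the study population's margins
#     (age 69.3 (SD 9.9), 49.9% female, 69.7% Medicare Advantage, Charlson
#     mean ~1.5, baseline exacerbations mean ~0.7, medication-class shares).
#   * A latent binary severity process S_t, first-order Markov and stationary,
#     independent of baseline covariates and never affected by treatment, so the
#     marginal per-month treatment effects below are exactly the planted ones.
#   * Monthly initiation hazard: logistic in baseline covariates, a month-1 vs
#     later-months intercept, and S_{t-1} scaled by `confounding_strength`.
#     Initiation is absorbing; trajectories that never initiate within follow-up
#     are rejected and redrawn (the cohort conditions on initiation), with the
#     number of redraws recorded in the truth ledger.
#   * Monthly severe-exacerbation hazard: logistic in covariates, S_{t-1}, an
#     untreated flag (log-OR `log_hr_untreated`) and its interaction with
#     centered month (`log_hr_untreated_by_month`). Moderate events follow a
#     severity-linked hazard unaffected by treatment.
#   * 12-month COPD-related cost: gamma with log-mean linear in covariates, the
#     mean of S over follow-up, and `beta_delay_cost` x (initiation month - 1);
#     non-COPD cost analogous, its delay slope derived so the implied all-cause
#     per-month ratio equals `allcause_ratio`.
#
# Severity leaves a claims footprint the pipeline can reconstruct exactly: a
# rescue-inhaler fill mid-month whenever S_t = 1 (and at day -15 for S_0), so
# the lag-1 rescue covariate in the person-month panel equals the true
# confounder. Moderate events that would chain-merge into a later severe event
# (within the episode gap before it) are suppressed at generation so that the
# first severe *episode* month equals the first severe *event* month and the
# planted hazard model is identifiable from the claims.
#
# The defaults keep the severity effect on the severe-event hazard moderate and
# put most of the confounding signal into the initiation hazard: with monthly
# event risks of ~1-3% the marginal (population-averaged) odds ratio then
# differs negligibly from the planted conditional one, so the weighted marginal
# fits target the planted values, while the unweighted fits remain clearly
# confounded.

#' Ground-truth parameter set for the synthetic-claims generator
#'
#' Defaults plant the study's reported effect sizes (per-month cost ratio 1.029
#' for COPD-related costs, all-cause ratio 1.028, untreated severe-exacerbation
#' OR 1.74 with per-month interaction 1.08) in a population whose baseline
#' margins match the study cohort.
#'
#' @param n_patients Number of synthetic patients.
#' @param beta_delay_cost Per-month log-cost effect of initiation delay on
#'   COPD-related costs.
#' @param allcause_ratio Target implied per-month ratio for all-cause costs
#'   (the non-COPD delay slope is derived from it).
#' @param log_hr_untreated Log odds ratio of severe exacerbation while
#'   untreated, at the centering month.
#' @param log_hr_untreated_by_month Interaction slope per month (centered).
#' @param confounding_strength Log-odds effect of the latent severity state on
#'   the initiation hazard (0 switches confounding off).
#' @param severity_outcome_logor Log-odds effect of severity on the severe-
#'   exacerbation hazard.
#' @param severity_cost_effect Log-cost effect of mean follow-up severity.
#' @param severity_prevalence Stationary P(S_t = 1).
#' @param severity_persistence P(S_t = 1 | S_{t-1} = 1).
#' @param cost_shape Gamma shape for cost draws.
#' @param mu0_copd,mu0_noncopd Log-scale cost intercepts (Month-1, covariates at
#'   reference, severity 0).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(n_patients = 2200L,
                         beta_delay_cost = log(1.029),
                         allcause_ratio = 1.028,
                         log_hr_untreated = log(1.74),
                         log_hr_untreated_by_month = log(1.08),
                         confounding_strength = 1.2,
                         severity_outcome_logor = 0.35,
                         severity_cost_effect = 0.6,
                         severity_prevalence = 0.3,
                         severity_persistence = 0.75,
                         cost_shape = 1.5,
                         mu0_copd = log(7500),
                         mu0_noncopd = log(5700),
                         seed = 1L) {
  stopifnot(n_patients > 0, cost_shape > 0,
            severity_prevalence > 0, severity_prevalence < 1,
            severity_persistence >= 0, severity_persistence <= 1)
  truth <- list(
    n_patients = as.integer(n_patients),
    beta_delay_cost = beta_delay_cost,
    allcause_ratio = allcause_ratio,
    log_hr_untreated = log_hr_untreated,
    log_hr_untreated_by_month = log_hr_untreated_by_month,
    confounding_strength = confounding_strength,
    severity_outcome_logor = severity_outcome_logor,
    severity_cost_effect = severity_cost_effect,
    severity_prevalence = severity_prevalence,
    severity_persistence = severity_persistence,
    cost_shape = cost_shape,
    mu0_copd = mu0_copd,
    mu0_noncopd = mu0_noncopd,
    # baseline margins (study Table-1-style targets)
    age_mean = 69.3, age_sd = 9.9, age_range = c(40, 95),
    pct_female = 0.499, pct_mapd = 0.697,
    charlson_nb_mu = 1.35, charlson_nb_size = 3,
    base_mod_rate = 0.6, base_sev_rate = 0.1,
    base_med_probs = c(lama = 0.284, ics = 0.063, ics_laba = 0.266,
                       ocs_systemic_cs = 0.380, saba = 0.409, sama = 0.030,
                       sama_saba = 0.115),
    emphysema_prob = 0.25,
    # marginal monthly initiation probabilities targeted at the average
    # patient: ~22% initiate in month 1 and ~60% by month 6, as in the study
    # population, with hazards rising late in follow-up so that almost every
    # trajectory initiates within the year (the cohort conditions on
    # initiation, and rejection redraws should stay rare)
    init_p_by_month = c(0.21, 0.135, 0.135, 0.135, 0.135, 0.135,
                        0.167, 0.20, 0.25, 0.33, 0.45, 0.45),
    # baseline hazards
    sev_logit0 = stats::qlogis(0.013),
    mod_logit0 = stats::qlogis(0.08), mod_severity_logor = 0.4,
    infection_prob_when_severe = 0.3,
    # covariate effects (age standardized by (age - mean)/sd; bexac = total
    # baseline exacerbation count)
    init_coef = c(age_std = 0.10, female = -0.05, mapd = 0.10,
                  charlson = 0.05, bexac = 0.10),
    sev_coef = c(age_std = 0.15, female = 0.00, mapd = 0.00,
                 charlson = 0.10, bexac = 0.20),
    cost_coef = c(age_std = 0.10, female = -0.05, mapd = 0.05,
                  charlson = 0.08, bexac = 0.10),
    seed = as.integer(seed)
  )
  structure(truth, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n_patients, x$seed))
  cat(sprintf("  per-month cost ratio (COPD): %.4f; implied all-cause: %.4f\n",
              exp(x$beta_delay_cost), x$allcause_ratio))
  cat(sprintf("  untreated severe-exacerbation OR: %.3f, per-month interaction: %.3f\n",
              exp(x$log_hr_untreated), exp(x$log_hr_untreated_by_month)))
  cat(sprintf("  confounding strength: %.2f\n", x$confounding_strength))
  invisible(x)
}

# Non-COPD per-month delay slope making the implied all-cause per-month ratio
# over the follow-up horizon match truth$allcause_ratio (component covariate
# effects are shared, so they cancel in the ratio).
derive_noncopd_delay <- function(truth, config = study_config()) {
  h <- config$followup_months - 1L
  A <- exp(truth$mu0_copd); B <- exp(truth$mu0_noncopd)
  num <- (A + B) * truth$allcause_ratio^h - A * exp(truth$beta_delay_cost)^h
  if (num <= 0) stop("allcause_ratio incompatible with COPD cost parameters")
  log(num / B) / h
}

# Charlson decomposition codes: one representative diagnosis code per condition
# (chronic pulmonary disease excluded: every patient carries a COPD code).
CHARLSON_DECOMP <- data.frame(
  condition = c("metastatic", "hiv", "severe_liver", "diabetes_comp", "hemiplegia",
                "renal", "malignancy", "mi", "chf", "pvd", "cvd", "dementia",
                "rheumatic", "ulcer", "mild_liver", "diabetes"),
  weight = c(6L, 6L, 3L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
  code = c("196", "042", "5722", "2504", "342", "585", "153", "410", "428",
           "441", "433", "290", "714", "531", "5712", "2500")
)

# Greedy decomposition of a target extra score into distinct condition codes.
charlson_codes_for <- function(score) {
  codes <- character(0)
  for (i in seq_len(nrow(CHARLSON_DECOMP))) {
    if (score <= 0) break
    if (CHARLSON_DECOMP$weight[i] <= score) {
      codes <- c(codes, CHARLSON_DECOMP$code[i])
      score <- score - CHARLSON_DECOMP$weight[i]
    }
  }
  codes
}

#' Generate a synthetic claims bundle with known ground truth
#'
#' See the file header for the data-generating model. Every generated patient
#' satisfies the eligibility criteria of [build_cohort()] by construction, and
#' the emitted claims reconstruct the latent quantities exactly: initiation
#' month from the first therapy fill, severity from mid-month rescue fills,
#' costs from dated medical claims summing to the drawn totals.
#'
#' @param truth A [ground_truth()].
#' @param config A [study_config()].
#' @return List with `bundle` (a validated `claims_bundle`) and `ledger` (a
#'   `data.table`, one row per patient, recording latent states: initiation
#'   month, severity path, planted event counts and dates, cost totals, number
#'   of rejection redraws).
#' @export
generate_bundle <- function(truth, config = study_config()) {
  set.seed(truth$seed)
  n <- truth$n_patients
  mlen <- config$month_length_days
  fm <- config$followup_months
  ids <- sprintf("P%06d", seq_len(n))

  ## ---- baseline covariates -------------------------------------------------
  age <- round(stats::rnorm(n, truth$age_mean, truth$age_sd))
  age <- pmin(pmax(age, truth$age_range[1]), truth$age_range[2])
  female <- stats::rbinom(n, 1, truth$pct_female)
  mapd <- stats::rbinom(n, 1, truth$pct_mapd)
  plan <- ifelse(mapd == 1, "medicare_advantage", "commercial")
  charlson_extra <- pmin(stats::rnbinom(n, mu = truth$charlson_nb_mu,
                                        size = truth$charlson_nb_size), 12L)
  base_mod <- stats::rpois(n, truth$base_mod_rate)
  base_sev <- stats::rpois(n, truth$base_sev_rate)
  bexac <- base_mod + base_sev
  emphysema <- stats::rbinom(n, 1, truth$emphysema_prob)

  # index dates uniform between plan formulary availability and a margin that
  # keeps every month-12 initiation fill inside the identification period
  last_index <- as.Date("2015-06-30")
  fs <- config$formulary_start[plan]
  index_date <- fs + floor(stats::runif(n) * (as.integer(last_index - fs) + 1))

  age_std <- (age - truth$age_mean) / truth$age_sd
  # the hazards and cost models use the Charlson score exactly as the pipeline
  # will measure it from claims: the chronic-pulmonary point is present for any
  # patient with a baseline COPD claim (i.e. any baseline exacerbation)
  charlson_obs <- pmax(charlson_extra, as.integer(bexac > 0L))
  lin <- function(coef) {
    coef[["age_std"]] * age_std + coef[["female"]] * female +
      coef[["mapd"]] * mapd + coef[["charlson"]] * charlson_obs +
      coef[["bexac"]] * bexac
  }
  v_init <- lin(truth$init_coef)
  v_sev <- lin(truth$sev_coef)
  v_cost <- lin(truth$cost_coef)

  ## ---- severity path + initiation month (rejection sampling) ---------------
  k <- truth$confounding_strength
  pi0 <- truth$severity_prevalence
  p11 <- truth$severity_persistence
  p01 <- pi0 * (1 - p11) / (1 - pi0)
  stopifnot(length(truth$init_p_by_month) == fm)
  a_month <- stats::qlogis(truth$init_p_by_month) - k * pi0

  draw_paths <- function(m) {
    S <- matrix(0L, m, fm + 1L)  # columns: S_0 .. S_fm
    S[, 1] <- stats::rbinom(m, 1, pi0)
    for (t in seq_len(fm)) {
      p <- ifelse(S[, t] == 1L, p11, p01)
      S[, t + 1L] <- stats::rbinom(m, 1, p)
    }
    S
  }
  draw_init <- function(S, v) {
    m <- nrow(S)
    init <- rep(NA_integer_, m)
    for (t in seq_len(fm)) {
      p <- stats::plogis(a_month[t] + v + k * S[, t])  # S_{t-1}
      hit <- is.na(init) & stats::runif(m) < p
      init[hit] <- t
    }
    init
  }

  S <- draw_paths(n)
  init_month <- draw_init(S, v_init)
  n_redraws <- integer(n)
  tries <- 0L
  while (anyNA(init_month)) {
    tries <- tries + 1L
    if (tries > 200L) {
      stop("initiation probability degenerate: trajectories never initiate ",
           "(no identifiability)")
    }
    todo <- which(is.na(init_month))
    n_redraws[todo] <- n_redraws[todo] + 1L
    S[todo, ] <- draw_paths(length(todo))
    init_month[todo] <- draw_init(S[todo, , drop = FALSE], v_init[todo])
  }

  ## ---- monthly events ------------------------------------------------------
  months <- seq_len(fm)
  untreated <- outer(init_month, months, function(m, t) as.integer(t < m))
  cmonth <- months - config$interaction_center_month
  Slag <- S[, months, drop = FALSE]  # S_{t-1} for month t
  eta_sev <- truth$sev_logit0 + v_sev +
    truth$severity_outcome_logor * Slag +
    truth$log_hr_untreated * untreated +
    truth$log_hr_untreated_by_month * untreated *
    matrix(cmonth, n, fm, byrow = TRUE)
  sev_event <- matrix(stats::rbinom(n * fm, 1, stats::plogis(eta_sev)), n, fm)
  eta_mod <- truth$mod_logit0 + truth$mod_severity_logor * Slag
  mod_event <- matrix(stats::rbinom(n * fm, 1, stats::plogis(eta_mod)), n, fm)

  # event day offsets within month bins (day >= 1 so no index-date events)
  sev_day <- matrix((months - 1L) * mlen, n, fm, byrow = TRUE) +
    matrix(sample.int(mlen - 1L, n * fm, replace = TRUE), n, fm)
  mod_day <- matrix((months - 1L) * mlen, n, fm, byrow = TRUE) +
    matrix(sample.int(mlen - 6L, n * fm, replace = TRUE), n, fm)

  # suppress moderate events that would chain-merge into a later severe event
  # (within episode_gap_days before it), so the first severe episode month
  # equals the first severe event month
  gap <- config$episode_gap_days
  keep_mod <- mod_event == 1L
  for (t in months) {
    if (!any(keep_mod[, t])) next
    near <- rep(FALSE, n)
    for (t2 in months) {
      d <- sev_day[, t2] - mod_day[, t]
      near <- near | (sev_event[, t2] == 1L & d >= 0L & d <= gap)
    }
    keep_mod[, t] <- keep_mod[, t] & !near
  }

  ## ---- costs ---------------------------------------------------------------
  smean <- rowMeans(S[, -1, drop = FALSE])
  beta_nc <- derive_noncopd_delay(truth, config)
  mu_copd <- exp(truth$mu0_copd + v_cost + truth$severity_cost_effect * smean +
                 truth$beta_delay_cost * (init_month - 1L))
  mu_nonc <- exp(truth$mu0_noncopd + v_cost + truth$severity_cost_effect * smean +
                 beta_nc * (init_month - 1L))
  shp <- truth$cost_shape
  copd_total <- stats::rgamma(n, shape = shp, scale = mu_copd / shp)
  nonc_total <- stats::rgamma(n, shape = shp, scale = mu_nonc / shp)

  ## ---- claims assembly -----------------------------------------------------
  med <- list(); rx <- list()
  add_med <- function(pid, day, dx, place, spec, paid) {
    med[[length(med) + 1L]] <<- data.table::data.table(
      patient_id = pid, service_date = index_date[match(pid, ids)] + day,
      dx_codes = dx, place = place, provider_specialty = spec, paid_total = paid)
  }
  add_rx <- function(pid, day, class, paid) {
    rx[[length(rx) + 1L]] <<- data.table::data.table(
      patient_id = pid, fill_date = index_date[match(pid, ids)] + day,
      drug_class = class, paid_total = paid)
  }

  copd_code <- ifelse(emphysema == 1L, "4928", "4919")

  # index visit (day 0): COPD visit with an eligible prescriber
  add_med(ids, 0L, copd_code, "office",
          sample(c("gp", "im", "pulm"), n, replace = TRUE), 0)

  # Charlson carrier claim (day -90): decomposition codes + a COPD code when the
  # target score is positive (the pulmonary point), non-prescriber specialty
  carrier_dx <- vapply(seq_len(n), function(i) {
    if (charlson_extra[i] == 0L) return("V700")
    paste(c("496", charlson_codes_for(charlson_extra[i] - 1L)), collapse = ";")
  }, character(1))
  add_med(ids, -90L, carrier_dx, "other", "lab", 0)

  # baseline exacerbations: severe = inpatient COPD claim; moderate = COPD
  # outpatient visit + corticosteroid fill the same day; days spread so that
  # distinct events do not chain-merge (>= gap+1 apart) and stay clear of the
  # S_0 rescue-signal window
  base_days <- seq(-config$baseline_months * mlen + 5L, -5L, by = gap + 1L)
  for (i in which(base_sev + base_mod > 0L)) {
    nev <- base_sev[i] + base_mod[i]
    days <- sample(base_days, min(nev, length(base_days)))
    nsev <- min(base_sev[i], length(days))
    if (nsev > 0L) add_med(rep(ids[i], nsev), days[seq_len(nsev)], "4919",
                           "inpatient", "hosp", 100)
    mdays <- days[setdiff(seq_along(days), seq_len(nsev))]
    if (length(mdays)) {
      add_med(rep(ids[i], length(mdays)), mdays, "4919", "office", "other_spec", 100)
      add_rx(rep(ids[i], length(mdays)), mdays, "ocs_systemic_cs", 30)
    }
  }

  # baseline medication-class fills; rescue classes stay out of the last
  # baseline month so the month-1 lagged rescue covariate equals S_0 exactly
  for (cls in names(truth$base_med_probs)) {
    p <- truth$base_med_probs[[cls]]
    rescue <- cls %in% c("saba", "sama", "sama_saba")
    if (cls == "saba") {
      # S_0 emits the rescue signal; top up to the target share among S_0 = 0
      p_extra <- max(0, (p - pi0) / (1 - pi0))
      has <- S[, 1] == 0L & stats::runif(n) < p_extra
    } else {
      has <- stats::runif(n) < p
    }
    if (any(has)) {
      lo <- -config$baseline_months * mlen + 1L
      hi <- if (rescue) -mlen - 1L else -1L
      add_rx(ids[has], sample(lo:hi, sum(has), replace = TRUE), cls, 50)
    }
  }

  # severity signal: rescue fill mid-month whenever S_t = 1 (and day -15 for S_0)
  s0 <- S[, 1] == 1L
  if (any(s0)) add_rx(ids[s0], -15L, "saba", 50)
  for (t in months) {
    on <- S[, t + 1L] == 1L
    if (any(on)) add_rx(ids[on], (t - 1L) * mlen + 15L, "saba", 50)
  }

  # respiratory-infection visits (extra severity footprint)
  inf <- matrix(stats::runif(n * fm) < truth$infection_prob_when_severe, n, fm) &
    S[, -1, drop = FALSE] == 1L
  for (t in months) {
    if (any(inf[, t])) {
      add_med(ids[inf[, t]], (t - 1L) * mlen + 10L, "486", "office", "other_spec", 0)
    }
  }

  # therapy fills: initiation at the start of the initiation-month bin, then
  # 30-day refills through the end of follow-up
  for (t in months) {
    on <- init_month <= t
    if (any(on)) add_rx(ids[on], (t - 1L) * mlen, "umec_vi", 300)
  }

  # follow-up exacerbation events
  for (t in months) {
    se <- sev_event[, t] == 1L
    if (any(se)) add_med(ids[se], sev_day[se, t], "4919", "inpatient", "hosp", NA_real_)
    mo <- keep_mod[, t]
    if (any(mo)) {
      add_med(ids[mo], mod_day[mo, t], "4919",
              sample(config$moderate_places, sum(mo), replace = TRUE),
              "other_spec", NA_real_)
      add_rx(ids[mo], mod_day[mo, t] + sample(0:2, sum(mo), replace = TRUE),
             "ocs_systemic_cs", 30)
    }
  }

  # cost filler claims, then distribute drawn totals over in-window claims
  add_med(ids, 100L, copd_code, "other", "lab", NA_real_)
  add_med(ids, 250L, copd_code, "other", "lab", NA_real_)
  add_med(ids, 80L, "4019", "other", "lab", NA_real_)
  add_med(ids, 300L, "2720", "other", "lab", NA_real_)

  medical <- data.table::rbindlist(med)
  pharmacy <- data.table::rbindlist(rx)

  # claims with paid_total = NA are cost carriers: split each patient's drawn
  # total over them (inpatient claims weighted heaviest), rounded to cents with
  # the remainder on the last claim so emitted totals are exact
  medical[, row_id := .I]
  medical[, copd := is_copd_claim(dx_codes, study_config())]
  carriers <- medical[is.na(paid_total)]
  carriers[, w := data.table::fifelse(place == "inpatient", 10, 3)]
  totals <- data.table::data.table(patient_id = ids, copd_total = copd_total,
                                   nonc_total = nonc_total)
  carriers <- totals[carriers, on = "patient_id"]
  carriers[, tot := data.table::fifelse(copd, copd_total, nonc_total)]
  carriers[, paid := {
    amt <- round(tot * w / sum(w), 2)
    amt[.N] <- round(tot[1] - sum(amt[-.N]), 2)
    amt
  }, by = .(patient_id, copd)]
  medical[carriers, on = "row_id", paid_total := i.paid]
  copd_emitted <- carriers[copd == TRUE, .(copd_cost = sum(paid)), by = patient_id]
  nonc_emitted <- carriers[copd == FALSE, .(nonc_cost = sum(paid)), by = patient_id]
  medical[, c("row_id", "copd") := NULL]

  ## ---- enrollment ----------------------------------------------------------
  cov_start <- pmin(fs, index_date - config$baseline_months * mlen) - 30L
  cov_end <- index_date + fm * mlen + 30L
  enrollment <- data.table::data.table(
    patient_id = ids, plan_type = plan, coverage_start = cov_start,
    coverage_end = cov_end, birth_year = as.integer(format(index_date, "%Y")) - age,
    sex = ifelse(female == 1L, "female", "male"))

  bundle <- claims_bundle(enrollment, medical, pharmacy)
  stopifnot(sum(vapply(attr(bundle, "rejected"), nrow, integer(1))) == 0L)

  first_sev_month <- apply(sev_event, 1L, function(z) {
    w <- which(z == 1L); if (length(w)) w[1] else NA_integer_
  })
  ledger <- data.table::data.table(
    patient_id = ids, index_date = index_date, initiation_month = init_month,
    age = age, female = female, mapd = mapd, charlson_extra = charlson_extra,
    charlson_obs = charlson_obs,
    base_mod = base_mod, base_sev = base_sev, emphysema = emphysema,
    severity_path = apply(S, 1L, paste, collapse = ""),
    smean = smean, n_redraws = n_redraws,
    n_severe_events = rowSums(sev_event),
    n_moderate_events = rowSums(keep_mod),
    first_severe_month = first_sev_month)
  ledger <- copd_emitted[ledger, on = "patient_id"]
  ledger <- nonc_emitted[ledger, on = "patient_id"]
  data.table::setnames(ledger, c("nonc_cost", "copd_cost"),
                       c("noncopd_cost_12m", "copd_cost_12m"))

  list(bundle = bundle, ledger = ledger)
}

#' Summarize baseline margins of a bundle
#'
#' Computes the population margins the generator targets (age mean/SD, % female,
#' % Medicare Advantage, mean Charlson score, mean baseline exacerbations) by
#' running index-date assignment and baseline measurement over all patients.
#'
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @return One-row `data.table` of margins plus `n`.
#' @export
summarize_margins <- function(bundle, config = study_config()) {
  if (nrow(bundle$enrollment) == 0L) stop("empty bundle: no patients")
  idx <- assign_index_date(bundle, config)
  birth <- bundle$enrollment[order(patient_id, coverage_start),
                             .SD[1L, .(birth_year, sex)], by = patient_id]
  rec <- birth[idx, on = "patient_id"]
  rec <- measure_baseline(rec, bundle, config)
  rec[, .(n = .N, age_mean = mean(age), age_sd = stats::sd(age),
          pct_female = 100 * mean(female), pct_mapd = 100 * mean(mapd),
          charlson_mean = mean(charlson),
          base_exac_mean = mean(base_sev_exac + base_mod_exac),
          base_sev_mean = mean(base_sev_exac), base_mod_mean = mean(base_mod_exac))]
}
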