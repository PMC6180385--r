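# New-user cohort construction: index dates, eligibility, month-of-initiation
# cohorts, baseline covariates, 12-month cost aggregation.
#
# Month grid: the index date is day 0; month m covers day offsets
# [(m-1)*month_length_days, m*month_length_days) (half-open bins), so a therapy
# fill on the index date is Month-1 initiation and a fill on day 359 is Month 12
# under the default 30-day month.

followup_end_offset <- function(config) {
  config$followup_months * config$month_length_days - 1L
}

#' Assign index dates
#'
#' The index date is the date of the first COPD-related medical claim with an
#' eligible prescriber specialty falling within
#' `[formulary_start(plan at visit), index_assignment_end]`. Patients with no
#' qualifying visit receive no index date (they are recorded in attrition by
#' [apply_eligibility()]). When overlapping enrollment spans give a visit an
#' ambiguous plan type, the earliest-starting span wins and the ambiguity is
#' counted in the `n_ambiguous_plan` attribute.
#'
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @return `data.table` with `patient_id`, `index_date`, `plan_type` (plan at
#'   the index visit).
#' @export
assign_index_date <- function(bundle, config = study_config()) {
  med <- bundle$medical[
    provider_specialty %in% config$prescriber_specialties &
      is_copd_claim(dx_codes, config) &
      service_date <= config$index_assignment_end,
    .(patient_id, service_date)]
  en <- bundle$enrollment[order(patient_id, coverage_start),
                          .(patient_id, plan_type, coverage_start, coverage_end)]
  med[, visit_date := service_date]
  hits <- en[med, on = .(patient_id, coverage_start <= visit_date,
                         coverage_end >= visit_date),
             nomatch = NULL, .(patient_id, service_date = i.service_date, plan_type)]
  n_amb <- nrow(hits) - nrow(unique(hits, by = c("patient_id", "service_date")))
  hits <- unique(hits, by = c("patient_id", "service_date"))  # earliest span wins
  hits <- hits[service_date >= config$formulary_start[plan_type]]
  out <- hits[order(patient_id, service_date),
              .SD[1L, .(index_date = service_date, plan_type)], by = patient_id]
  attr(out, "n_ambiguous_plan") <- n_amb
  out[]
}

#' Apply eligibility criteria
#'
#' Filters patients in order: qualifying index visit; age at least `min_age` in
#' the index year; at least one therapy (UMEC/VI) fill inside the patient-ID
#' period; at least one therapy fill within the follow-up window after index;
#' continuous enrollment from formulary availability through index and over the
#' baseline and follow-up windows; no baseline UMEC/VI or other LAMA/LABA
#' fixed-dose-combination fill. Filters never error: each criterion drops
#' patients and appends an attrition row.
#'
#' @param bundle A validated `claims_bundle`.
#' @param index_map Output of [assign_index_date()].
#' @param config A [study_config()].
#' @return List with `records` (patient_id, index_date, plan_type, birth_year,
#'   sex) and `attrition` (`data.table` of criterion label / n remaining).
#' @export
apply_eligibility <- function(bundle, index_map, config = study_config()) {
  mlen <- config$month_length_days
  all_ids <- unique(bundle$enrollment$patient_id)
  attr_rows <- list(list(criterion = "patients in enrollment", n = length(all_ids)))
  note <- function(label, n) {
    attr_rows[[length(attr_rows) + 1L]] <<- list(criterion = label, n = n)
  }

  rec <- data.table::as.data.table(index_map)
  note("qualifying COPD index visit with eligible prescriber", nrow(rec))

  birth <- bundle$enrollment[order(patient_id, coverage_start),
                             .SD[1L, .(birth_year, sex)], by = patient_id]
  rec <- birth[rec, on = "patient_id"]
  rec[, index_year := as.integer(format(index_date, "%Y"))]
  rec <- rec[index_year - birth_year >= config$min_age]
  note(sprintf("age >= %d in index year", config$min_age), nrow(rec))

  umec <- bundle$pharmacy[drug_class == "umec_vi", .(patient_id, fill_date)]
  in_id <- umec[fill_date >= config$id_period_start &
                  fill_date <= config$id_period_end, unique(patient_id)]
  rec <- rec[patient_id %chin% in_id]
  note("UMEC/VI fill in identification period", nrow(rec))

  rec[, fu_end := index_date + followup_end_offset(config)]
  fu_fill <- umec[rec, on = .(patient_id, fill_date >= index_date, fill_date <= fu_end),
                  nomatch = NULL, unique(patient_id)]
  rec <- rec[patient_id %chin% fu_fill]
  note("UMEC/VI fill within follow-up", nrow(rec))

  norm <- normalize_enrollment(bundle$enrollment, config$enrollment_gap_days)
  from <- pmin(config$formulary_start[rec$plan_type],
               rec$index_date - config$baseline_months * mlen)
  ok <- covers_interval(norm, rec$patient_id, from, rec$fu_end)
  rec <- rec[ok]
  note("continuous enrollment (formulary-to-index, baseline, follow-up)", nrow(rec))

  base_fdc <- bundle$pharmacy[drug_class %in% c("umec_vi", "lama_laba_fdc"),
                              .(patient_id, fill_date)]
  rec[, base_start := index_date - config$baseline_months * mlen]
  bad <- base_fdc[rec, on = .(patient_id, fill_date >= base_start, fill_date < index_date),
                  nomatch = NULL, unique(patient_id)]
  rec <- rec[!patient_id %chin% bad]
  note("no baseline UMEC/VI or LAMA/LABA FDC use", nrow(rec))

  records <- rec[, .(patient_id, index_date, plan_type, birth_year, sex)]
  attrition <- data.table::rbindlist(attr_rows)
  stopifnot(!is.unsorted(rev(attrition$n)))
  list(records = records, attrition = attrition)
}

#' Assign month-of-initiation cohorts
#'
#' Month of initiation is the half-open 30-day bin containing the first
#' follow-up therapy fill: `m = floor((fill - index)/month_length_days) + 1`, so
#' a fill on the index date is Month 1 and a fill on day 359 is Month 12.
#'
#' @param records Eligibility output (`records` element).
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @return `records` with `first_fill_date` and `initiation_month` added.
#' @export
assign_initiation_month <- function(records, bundle, config = study_config()) {
  rec <- data.table::as.data.table(records)
  rec[, fu_end := index_date + followup_end_offset(config)]
  umec <- bundle$pharmacy[drug_class == "umec_vi", .(patient_id, fill_date)]
  first_fill <- umec[rec, on = .(patient_id, fill_date >= index_date, fill_date <= fu_end),
                     nomatch = NULL, .(first_fill_date = min(x.fill_date)),
                     by = .EACHI][, .(patient_id, first_fill_date)]
  first_fill <- unique(first_fill, by = "patient_id")
  rec <- first_fill[rec, on = "patient_id"]
  stopifnot(!anyNA(rec$first_fill_date))  # eligibility guarantees a follow-up fill
  rec[, initiation_month :=
        as.integer(first_fill_date - index_date) %/% config$month_length_days + 1L]
  stopifnot(rec$initiation_month >= 1L, rec$initiation_month <= config$followup_months)
  rec[, fu_end := NULL]
  rec[]
}

#' Aggregate 12-month medical costs
#'
#' All-cause cost is the sum of `paid_total` (health-plan plus patient-paid)
#' over medical claims with service date in `[index, index + followup - 1]`
#' days; COPD-related cost restricts to claims carrying a COPD diagnosis in any
#' position. An optional deflator (named year -> factor map) is applied per
#' claim year before summation.
#'
#' @param records Cohort records with `index_date`.
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @param deflator Optional named numeric vector, names = calendar years.
#' @return `records` with `copd_cost_12m` and `allcause_cost_12m` added.
#' @export
aggregate_costs <- function(records, bundle, config = study_config(), deflator = NULL) {
  rec <- data.table::as.data.table(records)
  rec[, fu_end := index_date + followup_end_offset(config)]
  med <- bundle$medical[, .(patient_id, service_date, dx_codes, paid_total)]
  med[, copd := is_copd_claim(dx_codes, config)]
  if (!is.null(deflator)) {
    yr <- format(med$service_date, "%Y")
    f <- deflator[yr]
    f[is.na(f)] <- 1
    med[, paid_total := paid_total * as.numeric(f)]
  }
  inwin <- med[rec, on = .(patient_id, service_date >= index_date, service_date <= fu_end),
               nomatch = NULL, .(patient_id, paid_total = x.paid_total, copd = x.copd)]
  costs <- inwin[, .(allcause_cost_12m = sum(paid_total),
                     copd_cost_12m = sum(paid_total[copd])), by = patient_id]
  rec <- costs[rec, on = "patient_id"]
  rec[is.na(allcause_cost_12m), allcause_cost_12m := 0]
  rec[is.na(copd_cost_12m), copd_cost_12m := 0]
  rec[, fu_end := NULL]
  rec[]
}

# Per-patient Charlson score from the diagnosis codes observed in a claims
# subset (configurable prefix->weight condition map; each condition counted once).
charlson_scores <- function(claims, config) {
  if (nrow(claims) == 0L) {
    return(data.table::data.table(patient_id = character(0), charlson = integer(0)))
  }
  per_pat <- claims[, .(dx = paste(dx_codes, collapse = ";")), by = patient_id]
  cm <- config$charlson_map
  score <- integer(nrow(per_pat))
  for (i in seq_len(nrow(cm))) {
    score <- score + cm$weight[i] * dx_match_prefix(per_pat$dx, cm$prefixes[[i]])
  }
  data.table::data.table(patient_id = per_pat$patient_id, charlson = score)
}

#' Baseline covariate names
#'
#' The covariate set used by the treatment-selection and outcome models:
#' demographics, plan type, Charlson score, baseline exacerbation counts and
#' baseline medication-class indicators, plus an emphysema indicator.
#'
#' @param config A [study_config()] (unused; reserved for configurable lists).
#' @return Character vector of column names.
#' @export
baseline_covariate_names <- function(config = study_config()) {
  c("age", "female", "mapd", "charlson", "base_sev_exac", "base_mod_exac",
    "base_lama", "base_ics", "base_ics_laba", "base_ocs", "base_saba",
    "base_sama", "base_sama_saba", "emphysema")
}

#' Measure baseline covariates
#'
#' Assessed over the `baseline_months`-month window before index: age in the
#' index year (from birth year), sex, plan type, Charlson comorbidity score from
#' baseline diagnosis codes, baseline moderate/severe exacerbation episode
#' counts (via the episode algorithm on the baseline window), an indicator per
#' baseline medication class, and an emphysema diagnosis indicator (baseline
#' window through the index visit).
#'
#' @param records Cohort records with `index_date`, `birth_year`, `sex`,
#'   `plan_type`.
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @return `records` with one column per [baseline_covariate_names()].
#' @export
measure_baseline <- function(records, bundle, config = study_config()) {
  mlen <- config$month_length_days
  rec <- data.table::as.data.table(records)
  rec[, base_start := index_date - config$baseline_months * mlen]
  rec[, age := as.integer(format(index_date, "%Y")) - birth_year]
  rec[, female := as.integer(sex == "female")]
  rec[, mapd := as.integer(plan_type == "medicare_advantage")]

  base_med <- bundle$medical[rec, on = .(patient_id, service_date >= base_start,
                                         service_date < index_date),
                             nomatch = NULL, .(patient_id, dx_codes = x.dx_codes)]
  ch <- charlson_scores(base_med, config)
  rec <- ch[rec, on = "patient_id"]
  rec[is.na(charlson), charlson := 0L]

  # baseline exacerbation episodes (windowed per patient, then counted)
  ev <- detect_events(bundle, config, patients = rec$patient_id)
  ev <- ev[rec[, .(patient_id, base_start, index_date)], on = "patient_id", nomatch = NULL
           ][event_date >= base_start & event_date < index_date,
             .(patient_id, event_date, severity, source)]
  epi <- merge_episodes(ev, config)
  cnt <- epi[, .(base_sev_exac = sum(severity == "severe"),
                 base_mod_exac = sum(severity == "moderate")), by = patient_id]
  rec <- cnt[rec, on = "patient_id"]
  rec[is.na(base_sev_exac), base_sev_exac := 0L]
  rec[is.na(base_mod_exac), base_mod_exac := 0L]

  med_classes <- c(base_lama = "lama", base_ics = "ics", base_ics_laba = "ics_laba",
                   base_ocs = "ocs_systemic_cs", base_saba = "saba",
                   base_sama = "sama", base_sama_saba = "sama_saba")
  base_rx <- bundle$pharmacy[rec[, .(patient_id, base_start, index_date)],
                             on = .(patient_id, fill_date >= base_start,
                                    fill_date < index_date),
                             nomatch = NULL, .(patient_id, drug_class = x.drug_class)]
  for (col in names(med_classes)) {
    ids <- base_rx[drug_class == med_classes[[col]], unique(patient_id)]
    rec[, (col) := as.integer(patient_id %chin% ids)]
  }

  emph <- bundle$medical[rec[, .(patient_id, base_start, index_date)],
                         on = .(patient_id, service_date >= base_start,
                                service_date <= index_date),
                         nomatch = NULL, .(patient_id, dx_codes = x.dx_codes)]
  emph_ids <- emph[dx_match_prefix(dx_codes, config$emphysema_dx_prefixes),
                   unique(patient_id)]
  rec[, emphysema := as.integer(patient_id %chin% emph_ids)]
  rec[, base_start := NULL]
  rec[]
}

#' Build the analytic cohort
#'
#' Chains index-date assignment, eligibility, month-of-initiation assignment,
#' baseline covariate measurement, cost aggregation, follow-up episode
#' detection, and the same-month exacerbation/initiation reconciliation (if the
#' patient's earliest exacerbation episode in the initiation month predates the
#' first fill, initiation moves to the next month).
#'
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @param deflator Optional year -> factor cost deflator.
#' @return List: `cohort` (one row per patient with `initiation_month` already
#'   reconciled and `initiation_month_raw` preserved), `attrition`, `episodes`
#'   (follow-up exacerbation episodes), `monthly` (monthly episode indicators),
#'   `first_severe` (first severe episode table).
#' @export
build_cohort <- function(bundle, config = study_config(), deflator = NULL) {
  idx <- assign_index_date(bundle, config)
  elig <- apply_eligibility(bundle, idx, config)
  rec <- assign_initiation_month(elig$records, bundle, config)
  rec <- measure_baseline(rec, bundle, config)
  rec <- aggregate_costs(rec, bundle, config, deflator)

  # follow-up exacerbation episodes (events strictly after index)
  ev <- detect_events(bundle, config, patients = rec$patient_id)
  ev <- ev[rec[, .(patient_id, index_date,
                   fu_end = index_date + followup_end_offset(config))],
           on = "patient_id", nomatch = NULL
           ][event_date > index_date & event_date <= fu_end,
             .(patient_id, event_date, severity, source)]
  episodes <- merge_episodes(ev, config)
  monthly <- monthly_indicators(episodes, rec, config)
  first_sev <- first_severe_episode(episodes, rec, config)

  # same-month reconciliation: earliest episode of any severity in the raw
  # initiation month
  mlen <- config$month_length_days
  rec[, initiation_month_raw := initiation_month]
  epi <- rec[, .(patient_id, index_date, initiation_month_raw)][
    episodes, on = "patient_id", nomatch = NULL]
  epi[, month := as.integer(start_date - index_date) %/% mlen + 1L]
  same <- epi[month == initiation_month_raw,
              .(exac_date = min(start_date)), by = patient_id]
  rec <- same[rec, on = "patient_id"]
  rec[, initiation_month := {
    m <- reconcile_same_month(initiation_month_raw, exac_date, first_fill_date,
                              index_date, config)
    attributes(m) <- NULL
    m
  }]
  rec[, exac_date := NULL]
  data.table::setcolorder(rec, c("patient_id", "index_date", "plan_type",
                                 "initiation_month", "initiation_month_raw",
                                 "first_fill_date"))
  list(cohort = rec[], attrition = elig$attrition, episodes = episodes,
       monthly = monthly, first_severe = first_sev)
}
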