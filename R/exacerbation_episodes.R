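# Claims-based COPD exacerbation algorithm.
#
# Severe event: inpatient claim with a COPD diagnosis in any position.
# Moderate event: COPD-related ED / physician-office / urgent-care visit with a
#   systemic/oral corticosteroid or COPD-recommended antibiotic fill within
#   `rx_window_days` days on or after the visit (fills before the visit never
#   qualify: clinically the treatment follows the visit).
# Events within `episode_gap_days` days of each other chain-merge into a single
# episode classified by the highest-severity contributing event.

#' Detect exacerbation events
#'
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @param window Length-2 Date vector: events are restricted to
#'   `[window[1], window[2]]` (closed).
#' @param patients Optional character vector restricting to these patients.
#' @return `data.table` with columns `patient_id`, `event_date`, `severity`
#'   (`"severe"`/`"moderate"`), `source`; at most one event per patient, date
#'   and severity.
#' @export
detect_events <- function(bundle, config = study_config(), window = NULL,
                          patients = NULL) {
  med <- bundle$medical
  if (!is.null(patients)) med <- med[patient_id %chin% patients]
  copd <- med[is_copd_claim(dx_codes, config)]

  sev <- copd[place == "inpatient",
              .(patient_id, event_date = service_date,
                severity = "severe", source = "hospitalization")]

  mod_visits <- copd[place %in% config$moderate_places,
                     .(patient_id, event_date = service_date, source = place)]
  rx <- bundle$pharmacy[drug_class %in% config$exac_rx_classes,
                        .(patient_id, fill_date)]
  if (nrow(mod_visits) && nrow(rx)) {
    mod_visits[, lo := event_date]
    mod_visits[, hi := event_date + config$rx_window_days]
    qual <- rx[mod_visits, on = .(patient_id, fill_date >= lo, fill_date <= hi),
               nomatch = NULL,
               .(patient_id, event_date = i.event_date, source = i.source)]
    mod <- unique(qual)[, severity := "moderate"]
  } else {
    mod <- data.table::data.table(patient_id = character(0),
                                  event_date = as.Date(character(0)),
                                  source = character(0), severity = character(0))
  }

  ev <- data.table::rbindlist(list(sev, mod), use.names = TRUE)
  ev <- unique(ev, by = c("patient_id", "event_date", "severity"))
  if (!is.null(window)) {
    ev <- ev[event_date >= as.Date(window[1]) & event_date <= as.Date(window[2])]
  }
  data.table::setorder(ev, patient_id, event_date, severity)
  ev[]
}

#' Merge exacerbation events into episodes
#'
#' Chain rule: after sorting a patient's events by date, an event joins the open
#' episode iff its date is within `episode_gap_days` days (inclusive) of the
#' previous event; otherwise it opens a new episode. Episode severity is the
#' highest contributing severity. The operation is order-invariant in its input
#' and idempotent on episode start dates.
#'
#' @param events As from [detect_events()] (any row order).
#' @param config A [study_config()].
#' @return `data.table` with `patient_id`, `start_date`, `end_date`, `severity`,
#'   `n_events`, ordered and disjoint within patient.
#' @export
merge_episodes <- function(events, config = study_config()) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  start_date = as.Date(character(0)),
                                  end_date = as.Date(character(0)),
                                  severity = character(0), n_events = integer(0)))
  }
  ev <- ev[order(patient_id, event_date)]
  gap <- config$episode_gap_days
  ev[, epi := cumsum(c(1L, as.integer(diff(as.integer(event_date)) > gap))),
     by = patient_id]
  out <- ev[, .(start_date = min(event_date), end_date = max(event_date),
                severity = if (any(severity == "severe")) "severe" else "moderate",
                n_events = .N),
            by = .(patient_id, epi)][, epi := NULL]
  data.table::setorder(out, patient_id, start_date)
  out[]
}

#' Monthly exacerbation indicators over follow-up
#'
#' Assigns each episode to the 30-day month bin containing its start date
#' (day 1..`month_length_days` -> month 1, etc., with the index date day 0).
#' Episodes starting on the index date itself are excluded, as are episodes
#' outside months 1..`followup_months`.
#'
#' @param episodes As from [merge_episodes()].
#' @param index_dates `data.table`/data.frame with `patient_id`, `index_date`.
#' @param config A [study_config()].
#' @return `data.table` with `patient_id`, `month`, `n_episodes`, `n_severe`,
#'   `n_moderate` (only months with at least one episode appear).
#' @export
monthly_indicators <- function(episodes, index_dates, config = study_config()) {
  epi <- data.table::as.data.table(episodes)
  idx <- data.table::as.data.table(index_dates)[, .(patient_id, index_date)]
  epi <- idx[epi, on = "patient_id", nomatch = NULL]
  epi[, day := as.integer(start_date - index_date)]
  epi <- epi[day >= 1L]  # index-date episodes excluded
  epi[, month := day %/% config$month_length_days + 1L]
  epi <- epi[month <= config$followup_months]
  out <- epi[, .(n_episodes = .N,
                 n_severe = sum(severity == "severe"),
                 n_moderate = sum(severity == "moderate")),
             by = .(patient_id, month)]
  data.table::setorder(out, patient_id, month)
  out[]
}

#' First severe exacerbation episode per patient
#'
#' @inheritParams monthly_indicators
#' @return `data.table` with `patient_id`, `first_severe_date`,
#'   `first_severe_month` (one row per patient with a severe episode in
#'   follow-up months 1..followup_months).
#' @export
first_severe_episode <- function(episodes, index_dates, config = study_config()) {
  epi <- data.table::as.data.table(episodes)[severity == "severe"]
  idx <- data.table::as.data.table(index_dates)[, .(patient_id, index_date)]
  epi <- idx[epi, on = "patient_id", nomatch = NULL]
  epi[, day := as.integer(start_date - index_date)]
  epi <- epi[day >= 1L & day < config$followup_months * config$month_length_days]
  if (nrow(epi) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  first_severe_date = as.Date(character(0)),
                                  first_severe_month = integer(0)))
  }
  out <- epi[, .(first_severe_date = min(start_date)), by = patient_id]
  out <- idx[out, on = "patient_id"]
  out[, first_severe_month :=
        as.integer(first_severe_date - index_date) %/% config$month_length_days + 1L]
  out[, .(patient_id, first_severe_date, first_severe_month)]
}

#' Same-month exacerbation/initiation reconciliation
#'
#' If a patient has an exacerbation and initiates therapy in the same month bin,
#' and the exacerbation occurred strictly before the initiation fill, initiation
#' is reassigned to the following month (so the exacerbation is attributed to an
#' untreated month). Date ties leave the month unchanged ("prior" read
#' strictly). A reassignment beyond the last follow-up month is capped there
#' (no month `followup_months + 1` exists); the number of capped patients is
#' returned in the `n_capped` attribute.
#'
#' Vectorized over patients; `exac_date` is the start of the patient's earliest
#' exacerbation episode in the initiation month (`NA` if none).
#'
#' @param initiation_month Integer vector of initiation months.
#' @param exac_date,fill_date,index_date Date vectors (recycled as usual).
#' @param config A [study_config()].
#' @return Adjusted integer initiation months.
#' @export
reconcile_same_month <- function(initiation_month, exac_date, fill_date,
                                 index_date, config = study_config()) {
  mlen <- config$month_length_days
  exac_month <- as.integer(as.Date(exac_date) - as.Date(index_date)) %/% mlen + 1L
  bump <- !is.na(exac_date) & exac_month == initiation_month &
    as.Date(exac_date) < as.Date(fill_date)
  out <- initiation_month + as.integer(bump)
  capped <- out > config$followup_months
  out[capped] <- config$followup_months
  attr(out, "n_capped") <- sum(capped)
  out
}
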