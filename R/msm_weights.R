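# Person-month panel and stabilized, truncated inverse-probability-of-treatment
# weights from pooled monthly logistic treatment-selection models.
#
# Construction (treatment-initiation MSM, absorbing treatment):
#   * one row per patient per follow-up month; `treated` = 1 from the
#     (reconciled) initiation month onward; a patient is at risk of initiation
#     in months 1..initiation month;
#   * time-varying covariates L_t are measured over the *previous* month so
#     they are pre-treatment-decision information (month 1 uses the last
#     baseline month);
#   * both selection models are pooled logistic regressions over at-risk
#     person-months predicting initiation in month t: the numerator uses
#     baseline covariates plus flexible month terms, the denominator adds L_t;
#   * the stabilized weight is the cumulative product over months k <= t of
#     numerator/denominator likelihood contributions (p_k if initiation occurs
#     at k, 1 - p_k otherwise) and is frozen after initiation;
#   * weights are capped at a configurable upper percentile (linear
#     interpolation between order statistics) at analysis time.
# There are no censoring weights: the cohort requires continuous enrollment
# over the whole follow-up, so there is no dropout to weight for.

TIMEVARYING_COVARIATES <- c("exac_prev", "rescue_prev", "infection_prev")

#' Expand a cohort into a person-month panel
#'
#' @param cohort Cohort table from [build_cohort()] (needs `patient_id`,
#'   `index_date`, `initiation_month` and the baseline covariates).
#' @param episodes Follow-up exacerbation episodes from [build_cohort()].
#' @param bundle The validated `claims_bundle` (for lagged rescue-medication and
#'   respiratory-infection covariates).
#' @param config A [study_config()].
#' @return `data.table` with one row per patient per month 1..`followup_months`:
#'   `treated`, `at_risk`, `initiate`, lagged time-varying covariates
#'   (`exac_prev`, `rescue_prev`, `infection_prev`), `severe_event` (severe
#'   episode starting this month), `first_severe_month`, and the baseline
#'   covariates.
#' @export
expand_person_months <- function(cohort, episodes, bundle, config = study_config()) {
  mlen <- config$month_length_days
  fm <- config$followup_months
  co <- data.table::as.data.table(cohort)

  panel <- co[, .(month = seq_len(fm)),
              by = .(patient_id, index_date, initiation_month)]
  panel[, treated := as.integer(month >= initiation_month)]
  panel[, at_risk := as.integer(month <= initiation_month)]
  panel[, initiate := as.integer(month == initiation_month)]

  # lagged covariate windows: month t looks at day offsets
  # [(t-2)*mlen, (t-1)*mlen - 1] from index (t = 1 uses the last baseline month)
  offs <- function(dates, idx) as.integer(dates - idx)
  lag_flag <- function(tab, datecol) {
    x <- co[, .(patient_id, index_date)][tab, on = "patient_id", nomatch = NULL]
    x[, off := offs(get(datecol), index_date)]
    x <- x[off >= -mlen & off < (fm - 1L) * mlen]
    x[, month := off %/% mlen + 2L]  # covariate informs the *next* month
    unique(x[, .(patient_id, month)])
  }

  rescue <- lag_flag(bundle$pharmacy[drug_class %in% config$rescue_classes,
                                     .(patient_id, fill_date)], "fill_date")
  panel[, rescue_prev := 0L]
  panel[rescue, on = c("patient_id", "month"), rescue_prev := 1L]

  infect <- lag_flag(bundle$medical[dx_match_prefix(dx_codes, config$infection_dx_prefixes),
                                    .(patient_id, service_date)], "service_date")
  panel[, infection_prev := 0L]
  panel[infect, on = c("patient_id", "month"), infection_prev := 1L]

  # prior-month exacerbation episodes: follow-up episodes plus episodes starting
  # in the last baseline month
  ev <- detect_events(bundle, config, patients = co$patient_id)
  ev <- co[, .(patient_id, index_date)][ev, on = "patient_id", nomatch = NULL]
  ev <- ev[as.integer(event_date - index_date) >= -mlen &
             as.integer(event_date - index_date) < (fm - 1L) * mlen]
  epi <- merge_episodes(ev[, .(patient_id, event_date, severity, source)], config)
  exac <- lag_flag(epi[, .(patient_id, start_date)], "start_date")
  panel[, exac_prev := 0L]
  panel[exac, on = c("patient_id", "month"), exac_prev := 1L]

  mon <- monthly_indicators(episodes, co, config)
  panel[, severe_event := 0L]
  panel[mon[n_severe > 0L], on = c("patient_id", "month"), severe_event := 1L]
  fs <- first_severe_episode(episodes, co, config)
  panel[, first_severe_month := NA_integer_]
  panel[fs, on = "patient_id", first_severe_month := i.first_severe_month]

  vnames <- intersect(baseline_covariate_names(config), names(co))
  panel <- co[, c("patient_id", vnames), with = FALSE][panel, on = "patient_id"]
  data.table::setorder(panel, patient_id, month)
  panel[]
}

selection_formula <- function(config, timevarying = FALSE) {
  v <- baseline_covariate_names(config)
  month_term <- if (config$month_terms == "categorical") "factor(month)" else "month"
  rhs <- c(month_term, v, if (timevarying) TIMEVARYING_COVARIATES)
  stats::as.formula(paste("initiate ~", paste(rhs, collapse = " + ")))
}

#' Fit pooled monthly treatment-selection models
#'
#' Numerator: logistic regression of initiation on baseline covariates plus
#' flexible month terms, over at-risk person-months. Denominator: the same plus
#' the lagged time-varying covariates. Post-initiation months are excluded
#' (absorbing treatment).
#'
#' @param panel From [expand_person_months()].
#' @param config A [study_config()].
#' @return List of class `treatment_models` with elements `numerator`,
#'   `denominator` (fitted `glm`s) and `n_at_risk`.
#' @export
fit_treatment_models <- function(panel, config = study_config()) {
  ar <- panel[at_risk == 1L]
  if (sum(ar$initiate) < 1L) stop("panel has no initiation events")
  if (sum(ar$initiate == 0L) < 1L) {
    stop("no at-risk non-initiation person-months (e.g. all patients initiate ",
         "in month 1); treatment model is degenerate")
  }
  fit1 <- function(timevarying) {
    f <- selection_formula(config, timevarying)
    fit <- stats::glm(f, family = stats::binomial(), data = ar)
    if (!fit$converged) stop("treatment-selection model did not converge")
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    if (length(bad)) {
      stop("treatment-selection model is not identified; offending covariate(s): ",
           paste(bad, collapse = ", "))
    }
    fit
  }
  structure(list(numerator = fit1(FALSE), denominator = fit1(TRUE),
                 n_at_risk = nrow(ar)),
            class = "treatment_models")
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' For each patient and month t up to initiation, the contribution ratio is the
#' numerator-model likelihood of the observed initiation status over the
#' denominator-model likelihood; the stabilized weight is the running product,
#' frozen after initiation.
#'
#' @param panel From [expand_person_months()].
#' @param models From [fit_treatment_models()].
#' @param eps Guard band: denominator probabilities outside (eps, 1 - eps) are
#'   an error (advice: truncate or regularize).
#' @return The panel with columns `p_num`, `p_den` (at-risk months only) and
#'   `sw` (all months; frozen post-initiation).
#' @export
compute_stabilized_weights <- function(panel, models, eps = 1e-12) {
  panel <- data.table::copy(panel)
  ar <- panel$at_risk == 1L
  pn <- stats::predict(models$numerator, newdata = panel[ar], type = "response")
  pd <- stats::predict(models$denominator, newdata = panel[ar], type = "response")
  if (any(pd <= eps | pd >= 1 - eps)) {
    stop("denominator probabilities numerically 0 or 1; ",
         "consider truncation or regularizing the selection model")
  }
  panel[, c("p_num", "p_den") := NA_real_]
  panel[ar, p_num := pn]
  panel[ar, p_den := pd]
  panel[, ratio := data.table::fifelse(
    at_risk == 1L,
    data.table::fifelse(initiate == 1L, p_num / p_den, (1 - p_num) / (1 - p_den)),
    1.0)]
  panel[, sw := cumprod(ratio), by = patient_id]  # post-initiation ratio 1 = frozen
  panel[, ratio := NULL]
  panel[]
}

#' Truncate weights at an upper percentile
#'
#' The cap is the empirical `percentile` quantile of the weights (linear
#' interpolation between order statistics, the default quantile definition);
#' weights above it are set to the cap.
#'
#' @param w Numeric weight vector.
#' @param percentile Fraction in (0, 1), e.g. 0.999.
#' @return Truncated weights, with attributes `cap` and `n_capped`.
#' @export
truncate_weights <- function(w, percentile = 0.999) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 1) {
    stop("truncation percentile must lie strictly between 0 and 1")
  }
  if (!length(w)) stop("empty weight vector")
  cap <- unname(stats::quantile(w, percentile, type = 7))
  out <- pmin(w, cap)
  attr(out, "cap") <- cap
  attr(out, "n_capped") <- sum(w > cap)
  out
}

#' Weight diagnostics
#'
#' @param sw Numeric stabilized weights.
#' @param percentile Truncation percentile.
#' @return One-row `data.table`: mean, SD, min, max, cap, percent capped.
#' @export
weight_diagnostics <- function(sw, percentile = 0.999) {
  tw <- truncate_weights(sw, percentile)
  data.table::data.table(
    n = length(sw), mean = mean(sw), sd = stats::sd(sw),
    min = min(sw), max = max(sw),
    cap = attr(tw, "cap"),
    pct_capped = 100 * attr(tw, "n_capped") / length(sw))
}
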