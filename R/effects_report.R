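# Headline effect quantities and the run report: per-month percentage cost
# changes, adjusted Month-1 vs Month-12 costs by marginal standardization,
# their percentage difference, and the hazard-ratio-by-delay-month curve.

#' Adjusted 12-month cost at a given initiation month
#'
#' Marginal standardization over the weighted analytic cohort: every subject's
#' expected cost is predicted with initiation month set to `m` (all other
#' covariates at observed values) and averaged with the analysis weights. Under
#' the log link the ratio of two standardized costs reduces to
#' `exp((m2 - m1) * beta_month)` (covariates cancel).
#'
#' @param fit Cost `wgee` fit.
#' @param cohort Cohort table used for the fit.
#' @param weights Per-subject weights (output of [subject_weights()] or numeric
#'   aligned with `cohort`).
#' @param m Initiation month, 1..followup_months.
#' @param config A [study_config()].
#' @return Weighted mean expected cost (scalar).
#' @export
adjusted_cost_at_month <- function(fit, cohort, weights, m, config = study_config()) {
  if (m < 1 || m > config$followup_months) {
    stop("month out of range 1..", config$followup_months)
  }
  co <- data.table::as.data.table(cohort)
  if (is.data.frame(weights)) {
    co <- data.table::as.data.table(weights)[, .(patient_id, w = sw_trunc)][
      co, on = "patient_id"]
  } else co[, w := as.numeric(weights)]
  co[, initiation_month := m]
  mu <- predict(fit, co, type = "response")
  sum(co$w * mu) / sum(co$w)
}

#' Per-month percentage cost change
#'
#' `(exp(beta_month) - 1) * 100`, with the CI the monotone transform of the
#' coefficient's robust Wald CI. Also callable on a bare coefficient value
#' (returns the point percentage only), which is convenient for arithmetic
#' checks on printed results.
#'
#' @param fit A cost `wgee` fit, or a numeric log-scale per-month coefficient.
#' @param conf_level Confidence level.
#' @return Named numeric: `pct`, and for fits `lo`, `hi`.
#' @export
per_month_pct_change <- function(fit, conf_level = 0.95) {
  if (is.numeric(fit)) return(c(pct = 100 * (exp(fit) - 1)))
  tab <- wgee_table(fit, conf_level)[term == "initiation_month"]
  c(pct = 100 * (tab$ratio - 1), lo = 100 * (tab$ratio_lo - 1),
    hi = 100 * (tab$ratio_hi - 1))
}

#' Hazard-ratio-by-initiation-month curve
#'
#' @param fit Exacerbation `wgee` fit with interaction.
#' @param config A [study_config()].
#' @return `data.table` with `month`, `hr`, `lo`, `hi`.
#' @export
hr_curve <- function(fit, config = study_config()) {
  months <- seq_len(config$followup_months)
  hr <- hazard_ratio_at_month(fit, months, config)
  data.table::data.table(month = months, hr = hr[, "hr"], lo = hr[, "lo"],
                         hi = hr[, "hi"])
}

#' Assemble the effect report
#'
#' @param fit_cost_copd,fit_cost_allcause Cost `wgee` fits.
#' @param fit_exac Exacerbation fit with interaction.
#' @param fit_exac_noint Exacerbation fit without interaction.
#' @param cohort,weights As used for the cost fits.
#' @param config A [study_config()].
#' @param meta Named list of run metadata (seed, n, ...).
#' @return Object of class `effect_report`.
#' @export
build_effect_report <- function(fit_cost_copd, fit_cost_allcause, fit_exac,
                                fit_exac_noint, cohort, weights,
                                config = study_config(), meta = list()) {
  missing_parts <- c(
    if (is.null(fit_cost_copd)) "COPD cost fit",
    if (is.null(fit_cost_allcause)) "all-cause cost fit",
    if (is.null(fit_exac)) "exacerbation fit (interaction)",
    if (is.null(fit_exac_noint)) "exacerbation fit (no interaction)")
  if (length(missing_parts)) {
    stop("incomplete inputs; missing: ", paste(missing_parts, collapse = ", "))
  }
  fm <- config$followup_months
  adj <- function(fit) c(
    month1 = adjusted_cost_at_month(fit, cohort, weights, 1L, config),
    month12 = adjusted_cost_at_month(fit, cohort, weights, fm, config))
  adj_copd <- adj(fit_cost_copd)
  adj_all <- adj(fit_cost_allcause)
  noint <- wgee_table(fit_exac_noint)[term == "untreated"]
  structure(list(
    per_month_pct = list(copd = per_month_pct_change(fit_cost_copd),
                         allcause = per_month_pct_change(fit_cost_allcause)),
    adjusted_cost = list(copd = adj_copd, allcause = adj_all),
    pct_diff_12_vs_1 = c(copd = 100 * (adj_copd[["month12"]] / adj_copd[["month1"]] - 1),
                         allcause = 100 * (adj_all[["month12"]] / adj_all[["month1"]] - 1)),
    hr_curve = hr_curve(fit_exac, config),
    hr_untreated = hazard_ratio_at_month(fit_exac, config$interaction_center_month,
                                         config)[1, ],
    hr_interaction = {
      tab <- wgee_table(fit_exac)[term == "untreated_cmonth"]
      c(hr = tab$ratio, lo = tab$ratio_lo, hi = tab$ratio_hi)
    },
    hr_no_interaction = c(hr = noint$ratio, lo = noint$ratio_lo, hi = noint$ratio_hi),
    meta = meta
  ), class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat("<effect_report>\n")
  cat(sprintf("  COPD-related cost: +%.1f%% per month of delay; Month 12 vs 1: $%s vs $%s (+%.1f%%)\n",
              x$per_month_pct$copd[["pct"]],
              format(round(x$adjusted_cost$copd[["month12"]]), big.mark = ","),
              format(round(x$adjusted_cost$copd[["month1"]]), big.mark = ","),
              x$pct_diff_12_vs_1[["copd"]]))
  cat(sprintf("  all-cause cost:    +%.1f%% per month of delay; Month 12 vs 1: $%s vs $%s (+%.1f%%)\n",
              x$per_month_pct$allcause[["pct"]],
              format(round(x$adjusted_cost$allcause[["month12"]]), big.mark = ","),
              format(round(x$adjusted_cost$allcause[["month1"]]), big.mark = ","),
              x$pct_diff_12_vs_1[["allcause"]]))
  cat(sprintf("  untreated severe-exacerbation HR %.2f (%.2f-%.2f), per-month interaction %.2f (%.2f-%.2f)\n",
              x$hr_untreated[["hr"]], x$hr_untreated[["lo"]], x$hr_untreated[["hi"]],
              x$hr_interaction[["hr"]], x$hr_interaction[["lo"]], x$hr_interaction[["hi"]]))
  cat(sprintf("  HR without interaction: %.2f (%.2f-%.2f)\n",
              x$hr_no_interaction[["hr"]], x$hr_no_interaction[["lo"]],
              x$hr_no_interaction[["hi"]]))
  invisible(x)
}

#' Render the effect report to files
#'
#' Writes `report.json` (machine-readable, stable key order, display rounding:
#' whole dollars, percentages to 1 decimal, HRs to 2 decimals) and `report.txt`
#' (a human-readable summary). Two runs with the same seed and configuration
#' produce byte-identical output.
#'
#' @param report An `effect_report`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "effect_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- function(x, digits) lapply(as.list(x), round, digits = digits)
  r0 <- function(x) rd(x, 0); r1 <- function(x) rd(x, 1); r2 <- function(x) rd(x, 2)
  out <- list(
    per_month_pct = list(copd = r1(report$per_month_pct$copd),
                         allcause = r1(report$per_month_pct$allcause)),
    adjusted_cost = list(copd = r0(report$adjusted_cost$copd),
                         allcause = r0(report$adjusted_cost$allcause)),
    pct_diff_12_vs_1 = r1(report$pct_diff_12_vs_1),
    hr_untreated = r2(report$hr_untreated),
    hr_interaction = r2(report$hr_interaction),
    hr_no_interaction = r2(report$hr_no_interaction),
    hr_curve = lapply(seq_len(nrow(report$hr_curve)), function(i) {
      r2(report$hr_curve[i, .(month, hr, lo, hi)])
    }),
    meta = report$meta
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, open = "wt")
  sink(con); print(report); sink()
  close(con)
  invisible(c(json_path, txt_path))
}

#' Run the full MSM pipeline on a claims bundle
#'
#' Chains cohort construction, person-month expansion, treatment-selection
#' models, stabilized weights, the weighted outcome models and (optionally)
#' their unweighted counterparts for confounding diagnostics, and the effect
#' report.
#'
#' @param bundle A validated `claims_bundle`.
#' @param config A [study_config()].
#' @param naive Also fit unweighted outcome models (for bias diagnostics).
#' @param report Assemble the `effect_report` (requires all four fits).
#' @param meta Metadata passed into the report.
#' @return List with the cohort pieces, panel, models, weights, fits and report.
#' @export
run_msm_pipeline <- function(bundle, config = study_config(), naive = FALSE,
                             report = TRUE, meta = list()) {
  parts <- build_cohort(bundle, config)
  panel <- expand_person_months(parts$cohort, parts$episodes, bundle, config)
  models <- fit_treatment_models(panel, config)
  swpanel <- compute_stabilized_weights(panel, models)
  subj_w <- subject_weights(swpanel, config)

  fit_cost_copd <- fit_cost_model(parts$cohort, subj_w, "copd", config)
  fit_cost_all <- fit_cost_model(parts$cohort, subj_w, "allcause", config)
  fit_exac <- fit_exacerbation_model(swpanel, config, include_interaction = TRUE)
  fit_exac_noint <- fit_exacerbation_model(swpanel, config, include_interaction = FALSE)

  out <- list(cohort = parts$cohort, attrition = parts$attrition,
              episodes = parts$episodes, panel = panel, models = models,
              swpanel = swpanel, subject_weights = subj_w,
              fit_cost_copd = fit_cost_copd, fit_cost_allcause = fit_cost_all,
              fit_exac = fit_exac, fit_exac_noint = fit_exac_noint)
  if (naive) {
    ones <- rep(1, nrow(parts$cohort))
    out$naive_cost_copd <- fit_cost_model(parts$cohort, ones, "copd", config)
    out$naive_cost_allcause <- fit_cost_model(parts$cohort, ones, "allcause", config)
    out$naive_exac <- fit_exacerbation_model(
      swpanel, config, include_interaction = TRUE,
      weights = rep(1, nrow(swpanel)))
    out$naive_exac_noint <- fit_exacerbation_model(
      swpanel, config, include_interaction = FALSE,
      weights = rep(1, nrow(swpanel)))
  }
  if (report) {
    meta$n <- nrow(parts$cohort)
    out$report <- build_effect_report(fit_cost_copd, fit_cost_all, fit_exac,
                                      fit_exac_noint, parts$cohort, subj_w,
                                      config, meta)
  }
  out
}
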