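# Parameter-recovery studies on synthetic claims: the planted per-month cost
# effect and untreated severe-exacerbation effects are re-estimated by the full
# pipeline (generation -> cohort -> episodes -> weights -> outcome models),
# alongside unweighted fits that quantify the bias the planted time-varying
# confounding induces.

#' Replicate a parameter-recovery experiment
#'
#' For each replicate, generates a fresh synthetic bundle (seeds
#' `seed + 1 .. seed + reps`), runs the full MSM pipeline, and records the
#' weighted and unweighted estimates of the per-month log cost effect and the
#' untreated/interaction log odds ratios with their robust SEs.
#'
#' @param truth A [ground_truth()] template (its `n_patients`/`seed` are
#'   overridden per replicate).
#' @param config A [study_config()].
#' @param n Patients per replicate.
#' @param reps Number of replicates.
#' @param seed Base seed.
#' @param exacerbation Also fit the exacerbation models (slower).
#' @return `data.table`, one row per replicate: `beta_cost`, `se_cost`,
#'   `beta_cost_naive`, and when requested `beta_u`, `se_u`, `beta_u_naive`,
#'   `beta_int`, `se_int`, `beta_int_naive`.
#' @export
recovery_study <- function(truth = ground_truth(), config = study_config(),
                           n = 2000L, reps = 20L, seed = 20260101L,
                           exacerbation = TRUE) {
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    tr <- truth
    tr$n_patients <- as.integer(n)
    tr$seed <- as.integer(seed + r)
    gen <- generate_bundle(tr, config)
    res <- run_msm_pipeline(gen$bundle, config, naive = TRUE, report = FALSE)

    ctab <- wgee_table(res$fit_cost_copd)[term == "initiation_month"]
    ntab <- wgee_table(res$naive_cost_copd)[term == "initiation_month"]
    row <- data.table::data.table(
      rep = r, seed = tr$seed, n = nrow(res$cohort),
      beta_cost = ctab$estimate, se_cost = ctab$se_robust,
      beta_cost_naive = ntab$estimate)
    if (exacerbation) {
      et <- wgee_table(res$fit_exac)
      net <- wgee_table(res$naive_exac)
      row[, `:=`(
        beta_u = et[term == "untreated"]$estimate,
        se_u = et[term == "untreated"]$se_robust,
        beta_u_naive = net[term == "untreated"]$estimate,
        beta_int = et[term == "untreated_cmonth"]$estimate,
        se_int = et[term == "untreated_cmonth"]$se_robust,
        beta_int_naive = net[term == "untreated_cmonth"]$estimate)]
    }
    rows[[r]] <- row
  }
  data.table::rbindlist(rows)
}

#' Summarize a recovery study against the planted truth
#'
#' @param study Output of [recovery_study()].
#' @param truth The [ground_truth()] used.
#' @return One-row `data.table`: mean estimates, empirical SDs, mean absolute
#'   bias of weighted vs naive estimators, and 95% CI coverage of the planted
#'   values.
#' @export
summarize_recovery <- function(study, truth = ground_truth()) {
  zc <- stats::qnorm(0.975)
  covg <- function(est, se, target) mean(abs(est - target) <= zc * se)
  out <- data.table::data.table(
    reps = nrow(study),
    beta_cost_mean = mean(study$beta_cost),
    beta_cost_sd = stats::sd(study$beta_cost),
    bias_cost = mean(study$beta_cost) - truth$beta_delay_cost,
    bias_cost_naive = mean(study$beta_cost_naive) - truth$beta_delay_cost,
    coverage_cost = covg(study$beta_cost, study$se_cost, truth$beta_delay_cost))
  if ("beta_u" %in% names(study)) {
    out[, `:=`(
      beta_u_mean = mean(study$beta_u),
      bias_u = mean(study$beta_u) - truth$log_hr_untreated,
      bias_u_naive = mean(study$beta_u_naive) - truth$log_hr_untreated,
      coverage_u = covg(study$beta_u, study$se_u, truth$log_hr_untreated),
      beta_int_mean = mean(study$beta_int),
      bias_int = mean(study$beta_int) - truth$log_hr_untreated_by_month,
      coverage_int = covg(study$beta_int, study$se_int,
                          truth$log_hr_untreated_by_month))]
  }
  out[]
}
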