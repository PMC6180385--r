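# Weighted GEE outcome models with cluster sandwich variances.
#
# The cost outcome is one observation per subject: gamma distribution, log
# link, independence working correlation (forced: clusters are singletons),
# weighted by the subject's truncated stabilized weight at initiation, with the
# per-month cost ratio exp(beta_month) as the headline quantity. The
# severe-exacerbation outcome is a discrete-time first-event model: one row per
# subject per month until (and including) the month of the first severe
# exacerbation episode, logit link, an "untreated" flag and optionally its
# interaction with month centered at `interaction_center_month`, monthly
# truncated stabilized weights, robust variances clustered by subject.
# Exponentiated logit coefficients are reported as hazard ratios (the
# discrete-time approximation; monthly risks are small).
#
# No GEE solver ships with the package's dependencies, so the estimating
# equations (independence and exchangeable working correlations, moment
# estimation of the exchangeable correlation, Liang-Zeger sandwich) are solved
# here by Fisher scoring; tests cross-check the independence case against
# glm() + sandwich::vcovCL().

#' Weighted generalized estimating equations
#'
#' Fits a marginal regression with a working correlation structure and a
#' cluster-robust (sandwich) covariance. Supports prior (e.g. inverse
#' probability) weights, which enter the working variance like GLM prior
#' weights and propagate into the sandwich.
#'
#' @param formula Model formula.
#' @param data Data frame / data.table.
#' @param id Cluster identifier: a column name (string) or a vector.
#' @param weights Prior weights (vector or column name); default all 1.
#' @param family A [stats::family()] object; `Gamma(link = "log")` and
#'   `binomial()` are the supported, tested cases.
#' @param corstr Working correlation: `"independence"` or `"exchangeable"`.
#' @param maxit,tol Fisher-scoring controls.
#' @return Object of class `wgee`: coefficients, robust and model-based
#'   covariances, working-correlation estimate `alpha`, dispersion `phi`,
#'   cluster/observation counts.
#' @export
wgee <- function(formula, data, id, weights = NULL,
                 family = stats::gaussian(), corstr = c("independence", "exchangeable"),
                 maxit = 100L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  data <- as.data.frame(data)
  if (is.character(id) && length(id) == 1L) id <- data[[id]]
  if (is.character(weights) && length(weights) == 1L) weights <- data[[weights]]
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(id) == n, length(w) == n, all(w >= 0))

  # order by cluster so per-cluster sums are contiguous
  ord <- order(match(id, unique(id)))
  y <- y[ord]; X <- X[ord, , drop = FALSE]; w <- w[ord]; id <- id[ord]
  fid <- as.integer(factor(id, levels = unique(id)))
  nclus <- max(fid)
  csize <- tabulate(fid)
  alpha_min <- if (max(csize) > 1L) -1 / (max(csize) - 1L) + 1e-3 else -0.99

  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(X)) {
    mu0 <- family$linkfun(mean(if (family$family == "binomial") pmin(pmax(mean(y), 0.01), 0.99) else y))
    beta[match("(Intercept)", colnames(X))] <- mu0
  }
  alpha <- 0; phi <- 1
  converged <- FALSE

  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- family$linkinv(eta)
    dmu <- family$mu.eta(eta)
    a <- family$variance(mu) / w          # working variance with prior weights
    if (any(!is.finite(a)) || any(a <= 0)) {
      stop("wgee: non-finite or non-positive working variance; iteration trace: ",
           "it=", it, ", beta=", paste(signif(beta, 4), collapse = ","))
    }
    e <- y - mu
    rs <- e / sqrt(a)                     # standardized residuals
    phi <- sum(rs^2) / (n - p)

    if (corstr == "exchangeable") {
      # moment estimator over within-cluster pairs: sum_{j<k} r_j r_k
      sum_r <- rowsum(rs, fid)
      sum_r2 <- rowsum(rs^2, fid)
      npairs <- sum(csize * (csize - 1) / 2)
      alpha <- if (npairs > p) {
        sum((sum_r^2 - sum_r2) / 2) / (phi * (npairs - p))
      } else 0
      alpha <- min(max(alpha, alpha_min), 0.99)
    }

    Ds <- X * (dmu / sqrt(a))             # A^{-1/2} D
    z <- rs
    if (corstr == "exchangeable" && alpha != 0) {
      g <- alpha / (1 - alpha + csize * alpha)      # per cluster
      sum_Ds <- rowsum(Ds, fid)
      sum_z <- rowsum(z, fid)
      Ui_mat <- (rowsum(Ds * z, fid) - g * sum_Ds * drop(sum_z)) / (1 - alpha)
      U <- colSums(Ui_mat)
      H <- (crossprod(Ds) - crossprod(sum_Ds * g, sum_Ds)) / (1 - alpha)
    } else {
      Ui_mat <- rowsum(Ds * z, fid)
      U <- colSums(Ui_mat)
      H <- crossprod(Ds)
    }

    step <- tryCatch(solve(H, U), error = function(e2) {
      stop("wgee: singular working information (separation or collinearity); ",
           conditionMessage(e2))
    })
    beta <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("wgee did not converge in ", maxit, " iterations; ",
         "last step size ", signif(max(abs(step)), 3))
  }

  # sandwich at the solution (recompute pieces at final beta)
  eta <- drop(X %*% beta); mu <- family$linkinv(eta); dmu <- family$mu.eta(eta)
  a <- family$variance(mu) / w
  rs <- (y - mu) / sqrt(a)
  Ds <- X * (dmu / sqrt(a))
  if (corstr == "exchangeable" && alpha != 0) {
    g <- alpha / (1 - alpha + csize * alpha)
    sum_Ds <- rowsum(Ds, fid); sum_z <- rowsum(rs, fid)
    Ui_mat <- (rowsum(Ds * rs, fid) - g * sum_Ds * drop(sum_z)) / (1 - alpha)
    H <- (crossprod(Ds) - crossprod(sum_Ds * g, sum_Ds)) / (1 - alpha)
  } else {
    Ui_mat <- rowsum(Ds * rs, fid)
    H <- crossprod(Ds)
  }
  Hinv <- solve(H)
  vcov_robust <- Hinv %*% crossprod(Ui_mat) %*% Hinv
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    vcov_robust = vcov_robust,
    vcov_model = phi * Hinv,
    alpha = alpha, phi = phi, corstr = corstr, family = family,
    formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    n_obs = n, n_clusters = nclus, converged = converged, fitted_mu = mu,
    label = NULL
  ), class = "wgee")
}

#' @export
coef.wgee <- function(object, ...) object$coefficients

#' @export
vcov.wgee <- function(object, ...) object$vcov_robust

#' @export
predict.wgee <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, as.data.frame(newdata), xlev = object$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% object$coefficients)
  if (type == "response") object$family$linkinv(eta) else eta
}

#' Coefficient table with robust inference
#'
#' @param fit A `wgee` fit.
#' @param conf_level Confidence level for Wald intervals on robust SEs.
#' @return `data.table`: term, estimate, robust SE, z, p, CI bounds, and the
#'   exponentiated estimate and CI (ratio scale).
#' @export
wgee_table <- function(fit, conf_level = 0.95) {
  est <- coef(fit)
  se <- sqrt(diag(fit$vcov_robust))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  data.table::data.table(
    term = names(est), estimate = est, se_robust = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci_lo = est - zc * se, ci_hi = est + zc * se,
    ratio = exp(est), ratio_lo = exp(est - zc * se), ratio_hi = exp(est + zc * se))
}

#' @export
print.wgee <- function(x, ...) {
  cat("<wgee>", if (!is.null(x$label)) x$label, "\n")
  cat(sprintf("  family %s (%s link), working correlation: %s (alpha = %.3f)\n",
              x$family$family, x$family$link, x$corstr, x$alpha))
  cat(sprintf("  %d observations in %d clusters\n", x$n_obs, x$n_clusters))
  print(wgee_table(x)[, .(term, estimate, se_robust, p)], digits = 4)
  invisible(x)
}

#' Per-subject analysis weights for the cost model
#'
#' Extracts each subject's stabilized weight at the (reconciled) initiation
#' month from the weighted panel and truncates across subjects at the
#' configured percentile.
#'
#' @param swpanel Panel from [compute_stabilized_weights()].
#' @param config A [study_config()].
#' @return `data.table` with `patient_id`, `sw`, `sw_trunc`.
#' @export
subject_weights <- function(swpanel, config = study_config()) {
  w <- swpanel[initiate == 1L, .(patient_id, sw)]
  tw <- truncate_weights(w$sw, config$truncation_percentile)
  w[, sw_trunc := as.numeric(tw)]
  attr(w, "cap") <- attr(tw, "cap")
  w[]
}

#' Fit the 12-month cost model
#'
#' Weighted gamma GEE with log link, one observation per subject, independence
#' working correlation, robust SEs. The log-mean is linear in initiation month
#' (continuous) and the baseline covariates; `exp(coef["initiation_month"])` is
#' the per-month cost ratio of delaying initiation.
#'
#' Zero-cost subjects are incompatible with the gamma likelihood; per
#' `config$zero_cost`, either half the minimum positive cost is added to their
#' outcome (`"offset"`, default; count reported in the `n_zero_adjusted`
#' attribute) or the rows are dropped (`"drop"`).
#'
#' @param cohort Cohort table from [build_cohort()] (with costs and covariates).
#' @param weights Per-subject weights: output of [subject_weights()] or a
#'   numeric vector aligned with `cohort` rows.
#' @param outcome `"copd"` or `"allcause"`.
#' @param config A [study_config()].
#' @return A `wgee` fit (label `cost-<outcome>`).
#' @export
fit_cost_model <- function(cohort, weights, outcome = c("copd", "allcause"),
                           config = study_config()) {
  outcome <- match.arg(outcome)
  co <- data.table::as.data.table(cohort)
  ycol <- if (outcome == "copd") "copd_cost_12m" else "allcause_cost_12m"
  co[, cost := get(ycol)]
  if (all(co$cost == 0)) stop("all-zero cost outcome")
  if (is.data.frame(weights)) {
    co <- data.table::as.data.table(weights)[, .(patient_id, w = sw_trunc)][
      co, on = "patient_id"]
  } else co[, w := as.numeric(weights)]
  stopifnot(!anyNA(co$w))

  n_zero <- sum(co$cost == 0)
  if (n_zero > 0L) {
    if (config$zero_cost == "offset") {
      co[cost == 0, cost := min(co$cost[co$cost > 0]) / 2]
    } else co <- co[cost > 0]
  }
  f <- stats::as.formula(paste("cost ~ initiation_month +",
                               paste(baseline_covariate_names(config), collapse = " + ")))
  fit <- wgee(f, co, id = co$patient_id, weights = co$w,
              family = stats::Gamma(link = "log"), corstr = "independence")
  fit$label <- paste0("cost-", outcome)
  attr(fit, "n_zero_adjusted") <- n_zero
  fit
}

#' Fit the monthly first-severe-exacerbation model
#'
#' Discrete-time first-event analysis: subjects contribute one row per month
#' until and including the month of their first severe exacerbation episode,
#' then exit the risk set. The logit of the event is modelled on the untreated
#' flag (1 until the month before initiation), optionally its interaction with
#' month centered at `config$interaction_center_month`, and the baseline
#' covariates, with monthly truncated stabilized weights and robust SEs
#' clustered by subject. Exponentiated coefficients approximate hazard ratios.
#'
#' @param panel Panel from [compute_stabilized_weights()] (carries `sw`,
#'   `severe_event`, `first_severe_month`, `treated`).
#' @param config A [study_config()].
#' @param include_interaction Include the untreated-by-centered-month term.
#' @param weights Optional numeric vector aligned with `panel` rows overriding
#'   `panel$sw` (truncation is applied to the risk-set rows either way).
#' @param corstr Working correlation for the person-month cluster.
#' @return A `wgee` fit (label `exacerbation` / `exacerbation-nointeraction`).
#' @export
fit_exacerbation_model <- function(panel, config = study_config(),
                                   include_interaction = TRUE, weights = NULL,
                                   corstr = c("exchangeable", "independence")) {
  corstr <- match.arg(corstr)
  pm <- data.table::copy(data.table::as.data.table(panel))
  if (!is.null(weights)) pm[, sw := as.numeric(weights)]
  pm <- pm[is.na(first_severe_month) | month <= first_severe_month]
  pm[, event := as.integer(!is.na(first_severe_month) & month == first_severe_month)]
  if (sum(pm$event) == 0L) stop("no severe exacerbation events in panel")
  pm[, untreated := 1L - treated]
  pm[, untreated_cmonth := untreated * (month - config$interaction_center_month)]
  pm[, w := as.numeric(truncate_weights(sw, config$truncation_percentile))]

  rhs <- c("untreated", if (include_interaction) "untreated_cmonth",
           baseline_covariate_names(config))
  f <- stats::as.formula(paste("event ~", paste(rhs, collapse = " + ")))
  fit <- wgee(f, pm, id = pm$patient_id, weights = pm$w,
              family = stats::binomial(), corstr = corstr)
  fit$label <- if (include_interaction) "exacerbation" else "exacerbation-nointeraction"
  fit
}

#' Hazard ratio at a given initiation-delay month
#'
#' For the interaction model, `HR(m) = exp(b_untreated + b_interaction *
#' (m - center))`, with a delta-method CI on the robust covariance.
#'
#' @param fit Exacerbation `wgee` fit with the interaction term.
#' @param m Month 1..followup_months.
#' @param config A [study_config()].
#' @param conf_level Confidence level.
#' @return Named numeric: `hr`, `lo`, `hi`.
#' @export
hazard_ratio_at_month <- function(fit, m, config = study_config(), conf_level = 0.95) {
  if (any(m < 1 | m > config$followup_months)) {
    stop("month out of range 1..", config$followup_months)
  }
  b <- coef(fit)
  if (!all(c("untreated", "untreated_cmonth") %in% names(b))) {
    stop("fit does not include the untreated-by-month interaction")
  }
  V <- fit$vcov_robust[c("untreated", "untreated_cmonth"),
                       c("untreated", "untreated_cmonth")]
  d <- m - config$interaction_center_month
  lhr <- b[["untreated"]] + b[["untreated_cmonth"]] * d
  se <- sqrt(V[1, 1] + d^2 * V[2, 2] + 2 * d * V[1, 2])
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  cbind(hr = exp(lhr), lo = exp(lhr - zc * se), hi = exp(lhr + zc * se))
}
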