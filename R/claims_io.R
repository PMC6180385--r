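# Claims tables, study configuration, and validation.
#
# The pipeline consumes three delimited-text tables (canonical dialect: UTF-8,
# comma-delimited, ISO-8601 dates, header row required):
#   enrollment.csv: patient_id, plan_type, coverage_start, coverage_end, birth_year, sex
#   medical.csv:    patient_id, service_date, dx_codes (";"-separated, any position),
#                   place, provider_specialty, paid_total
#   pharmacy.csv:   patient_id, fill_date, drug_class, paid_total
# Diagnosis codes are matched case-insensitively by prefix with punctuation stripped,
# so the usual claims wildcards ("491.xx", "J44*") are stored as prefixes "491", "J44".

PLAN_TYPES <- c("commercial", "medicare_advantage")
SEX_LEVELS <- c("female", "male")
PLACE_LEVELS <- c("inpatient", "ed", "office", "urgent_care", "other")
DRUG_CLASSES <- c(
  "umec_vi", "lama", "laba", "lama_laba_fdc", "ics", "ics_laba",
  "ocs_systemic_cs", "copd_antibiotic", "saba", "sama", "sama_saba", "other"
)

#' Default Charlson comorbidity condition map
#'
#' A condition -> (diagnosis-code prefixes, weight) table using the classic
#' 17-condition weighting on ICD-9-CM code prefixes. The map is configurable
#' because published claims implementations differ in granularity; this default
#' is a reasonable approximation, not a validated grouper.
#'
#' @return A `data.frame` with columns `condition`, `weight` and `prefixes`
#'   (a list column of character prefixes).
#' @export
default_charlson_map <- function() {
  cond <- list(
    mi            = list(1L, c("410", "412")),
    chf           = list(1L, c("428")),
    pvd           = list(1L, c("441", "4439", "7854")),
    cvd           = list(1L, c("430", "431", "432", "433", "434", "435", "436", "437", "438")),
    dementia      = list(1L, c("290")),
    chronic_pulm  = list(1L, c("490", "491", "492", "493", "494", "495", "496",
                               "500", "501", "502", "503", "504", "505")),
    rheumatic     = list(1L, c("7100", "7101", "7104", "714")),
    ulcer         = list(1L, c("531", "532", "533", "534")),
    mild_liver    = list(1L, c("5712", "5714", "5715", "5716")),
    diabetes      = list(1L, c("2500", "2501", "2502", "2503", "2507")),
    diabetes_comp = list(2L, c("2504", "2505", "2506")),
    hemiplegia    = list(2L, c("342", "3441")),
    renal         = list(2L, c("582", "583", "585", "586", "588")),
    malignancy    = list(2L, c("14", "15", "16", "170", "171", "172", "174", "175",
                               "179", "180", "181", "182", "183", "184", "185", "186",
                               "187", "188", "189", "190", "191", "192", "193", "194",
                               "195", "200", "201", "202", "203", "204", "205", "206",
                               "207", "208")),
    severe_liver  = list(3L, c("5722", "5723", "5724", "5728")),
    metastatic    = list(6L, c("196", "197", "198", "199")),
    hiv           = list(6L, c("042", "043", "044"))
  )
  data.frame(
    condition = names(cond),
    weight = unname(vapply(cond, function(x) x[[1]], integer(1))),
    prefixes = I(unname(lapply(cond, function(x) x[[2]]))),
    row.names = NULL
  )
}

#' Study configuration
#'
#' Bundles every tunable of the study design: identification and index-assignment
#' windows, per-plan formulary availability dates, baseline/follow-up window
#' lengths on the 30-day month grid, diagnosis-code prefix lists, the exacerbation
#' algorithm's prescription window and episode-merge gap, and the weighting /
#' modelling knobs (truncation percentile, interaction centering month).
#'
#' All date intervals are closed on both ends unless an operation states
#' otherwise; months are fixed-length bins of `month_length_days` days from the
#' index date, with the index date itself day 0 of month 1.
#'
#' @param id_period_start,id_period_end Patient-identification period (therapy
#'   fills must occur inside it).
#' @param index_assignment_end Last admissible index date.
#' @param formulary_start Named character/Date vector mapping plan type to the
#'   formulary availability date of the therapy.
#' @param baseline_months,followup_months,month_length_days Study window grid.
#' @param min_age Minimum age (years) in the index year.
#' @param rx_window_days Maximum days from a qualifying outpatient visit to a
#'   corticosteroid/antibiotic fill for a moderate exacerbation (inclusive).
#' @param episode_gap_days Maximum gap (days) between consecutive exacerbation
#'   events merged into one episode (inclusive).
#' @param truncation_percentile Upper percentile at which stabilized weights are
#'   capped, in (0, 1).
#' @param interaction_center_month Month at which the untreated-by-month
#'   interaction is centered.
#' @param enrollment_gap_days Maximum coverage gap (days) still counted as
#'   continuous enrollment; 0 is the strictest reading.
#' @param copd_dx_prefixes Diagnosis-code prefixes identifying COPD (punctuation
#'   stripped, case-insensitive).
#' @param infection_dx_prefixes Prefixes identifying acute respiratory infection
#'   visits (a time-varying severity covariate).
#' @param emphysema_dx_prefixes Prefixes identifying emphysema.
#' @param prescriber_specialties Provider-specialty codes eligible to anchor the
#'   index visit.
#' @param exac_rx_classes Pharmacy classes qualifying a moderate exacerbation.
#' @param rescue_classes Pharmacy classes counted as rescue medication.
#' @param moderate_places Places of service eligible for moderate exacerbation
#'   events.
#' @param charlson_map Condition map as from [default_charlson_map()].
#' @param month_terms How calendar month enters the treatment-selection models:
#'   `"categorical"` (default) or `"linear"`.
#' @param zero_cost Handling of zero-cost subjects under the gamma/log outcome
#'   model: `"offset"` adds half the minimum positive cost, `"drop"` removes them.
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(id_period_start = "2014-04-28",
                         id_period_end = "2016-07-31",
                         index_assignment_end = "2015-09-30",
                         formulary_start = c(commercial = "2014-04-28",
                                             medicare_advantage = "2015-01-01"),
                         baseline_months = 6L,
                         followup_months = 12L,
                         month_length_days = 30L,
                         min_age = 40L,
                         rx_window_days = 5L,
                         episode_gap_days = 14L,
                         truncation_percentile = 0.999,
                         interaction_center_month = 6L,
                         enrollment_gap_days = 0L,
                         copd_dx_prefixes = c("491", "492", "4932", "496",
                                              "J41", "J42", "J43", "J44"),
                         infection_dx_prefixes = c("466", "480", "481", "482", "483",
                                                   "484", "485", "486", "487", "488",
                                                   "J09", "J10", "J11", "J12", "J13",
                                                   "J14", "J15", "J16", "J17", "J18",
                                                   "J20", "J21", "J22"),
                         emphysema_dx_prefixes = c("492", "J43"),
                         prescriber_specialties = c("gp", "im", "pulm", "card",
                                                    "allergy", "ent", "obgyn", "em"),
                         exac_rx_classes = c("ocs_systemic_cs", "copd_antibiotic"),
                         rescue_classes = c("saba", "sama", "sama_saba"),
                         moderate_places = c("ed", "office", "urgent_care"),
                         charlson_map = default_charlson_map(),
                         month_terms = c("categorical", "linear"),
                         zero_cost = c("offset", "drop")) {
  cfg <- list(
    id_period_start = as.Date(id_period_start),
    id_period_end = as.Date(id_period_end),
    index_assignment_end = as.Date(index_assignment_end),
    formulary_start = stats::setNames(as.Date(formulary_start), names(formulary_start)),
    baseline_months = as.integer(baseline_months),
    followup_months = as.integer(followup_months),
    month_length_days = as.integer(month_length_days),
    min_age = as.integer(min_age),
    rx_window_days = as.integer(rx_window_days),
    episode_gap_days = as.integer(episode_gap_days),
    truncation_percentile = truncation_percentile,
    interaction_center_month = as.integer(interaction_center_month),
    enrollment_gap_days = as.integer(enrollment_gap_days),
    copd_dx_prefixes = normalize_code(copd_dx_prefixes),
    infection_dx_prefixes = normalize_code(infection_dx_prefixes),
    emphysema_dx_prefixes = normalize_code(emphysema_dx_prefixes),
    prescriber_specialties = prescriber_specialties,
    exac_rx_classes = exac_rx_classes,
    rescue_classes = rescue_classes,
    moderate_places = moderate_places,
    charlson_map = charlson_map,
    month_terms = match.arg(month_terms),
    zero_cost = match.arg(zero_cost)
  )
  stopifnot(
    cfg$id_period_start <= cfg$id_period_end,
    all(!is.na(cfg$formulary_start)),
    cfg$baseline_months > 0, cfg$followup_months > 0, cfg$month_length_days > 0,
    cfg$rx_window_days >= 0, cfg$episode_gap_days >= 0,
    cfg$truncation_percentile > 0, cfg$truncation_percentile < 1,
    cfg$interaction_center_month >= 1,
    cfg$interaction_center_month <= cfg$followup_months
  )
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  index window:", format(min(x$formulary_start)), "to",
      format(x$index_assignment_end), "\n")
  cat("  baseline/follow-up:", x$baseline_months, "/", x$followup_months,
      "months of", x$month_length_days, "days\n")
  cat("  COPD dx prefixes:", paste(x$copd_dx_prefixes, collapse = ", "), "\n")
  cat("  weight truncation percentile:", x$truncation_percentile, "\n")
  invisible(x)
}

#' Write / read a study configuration as YAML
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return `read_config` returns a `study_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$id_period_start <- format(x$id_period_start)
  x$id_period_end <- format(x$id_period_end)
  x$index_assignment_end <- format(x$index_assignment_end)
  x$formulary_start <- as.list(stats::setNames(format(x$formulary_start),
                                               names(x$formulary_start)))
  x$charlson_map <- lapply(seq_len(nrow(config$charlson_map)), function(i) {
    list(condition = config$charlson_map$condition[i],
         weight = config$charlson_map$weight[i],
         prefixes = config$charlson_map$prefixes[[i]])
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cm <- x$charlson_map
  x$charlson_map <- data.frame(
    condition = vapply(cm, `[[`, character(1), "condition"),
    weight = vapply(cm, function(e) as.integer(e$weight), integer(1)),
    prefixes = I(lapply(cm, function(e) as.character(e$prefixes)))
  )
  x$formulary_start <- unlist(x$formulary_start)
  do.call(study_config, x)
}

# Strip punctuation and upper-case a diagnosis code or prefix.
normalize_code <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

#' Match diagnosis codes against a prefix list
#'
#' Vectorized over `dx`, a character vector in which each element holds one or
#' more ";"-separated diagnosis codes (any claim position). Matching is
#' case-insensitive prefix matching after stripping punctuation, which
#' implements the usual claims wildcards ("491.xx" -> prefix "491").
#'
#' @param dx Character vector of ";"-separated code lists.
#' @param prefixes Character vector of code prefixes (normalized or not).
#' @return Logical vector: element i is `TRUE` iff any code in `dx[i]` starts
#'   with any prefix.
#' @export
dx_match_prefix <- function(dx, prefixes) {
  if (length(dx) == 0L) return(logical(0))
  prefixes <- normalize_code(prefixes)
  codes <- strsplit(as.character(dx), ";", fixed = TRUE)
  idx <- rep.int(seq_along(codes), lengths(codes))
  flat <- normalize_code(unlist(codes, use.names = FALSE))
  hit <- rep(FALSE, length(flat))
  for (p in prefixes) hit <- hit | startsWith(flat, p)
  out <- rep(FALSE, length(dx))
  if (length(flat)) out[unique(idx[hit])] <- TRUE
  out
}

#' Is a medical claim COPD-related?
#'
#' A claim is COPD-related iff any of its diagnosis codes, in any position,
#' matches a configured COPD code prefix.
#'
#' @param dx_codes Character vector of ";"-separated diagnosis-code lists (one
#'   element per claim).
#' @param config A [study_config()].
#' @return Logical vector.
#' @export
is_copd_claim <- function(dx_codes, config = study_config()) {
  dx_match_prefix(dx_codes, config$copd_dx_prefixes)
}

#' Construct a claims bundle
#'
#' @param enrollment,medical,pharmacy Data frames with the canonical schemas.
#' @param validate Validate row invariants (default `TRUE`).
#' @return A `claims_bundle`: list of three `data.table`s with attributes
#'   `rejected` (row-level diagnostics) when validated.
#' @export
claims_bundle <- function(enrollment, medical, pharmacy, validate = TRUE) {
  b <- structure(
    list(enrollment = data.table::as.data.table(enrollment),
         medical = data.table::as.data.table(medical),
         pharmacy = data.table::as.data.table(pharmacy)),
    class = "claims_bundle"
  )
  if (validate) b <- validate_bundle(b) else b
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  %d patients, %d enrollment spans, %d medical claims, %d pharmacy claims\n",
              length(unique(x$enrollment$patient_id)), nrow(x$enrollment),
              nrow(x$medical), nrow(x$pharmacy)))
  rej <- attr(x, "rejected")
  if (!is.null(rej)) {
    nr <- sum(vapply(rej, nrow, integer(1)))
    cat("  rejected rows:", nr, "\n")
  }
  invisible(x)
}

BUNDLE_SCHEMAS <- list(
  enrollment = c("patient_id", "plan_type", "coverage_start", "coverage_end",
                 "birth_year", "sex"),
  medical = c("patient_id", "service_date", "dx_codes", "place",
              "provider_specialty", "paid_total"),
  pharmacy = c("patient_id", "fill_date", "drug_class", "paid_total")
)

parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

# Validate one table; returns list(kept, rejected) where rejected carries
# `row` (1-based data row number) and `reason`.
validate_table <- function(dt, table) {
  cols <- BUNDLE_SCHEMAS[[table]]
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("schema error in %s table: missing column(s) %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  dt <- data.table::copy(dt[, cols, with = FALSE])
  n <- nrow(dt)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why

  if (table == "enrollment") {
    dt[, coverage_start := parse_iso_date(coverage_start)]
    dt[, coverage_end := parse_iso_date(coverage_end)]
    flag(is.na(dt$coverage_start) | is.na(dt$coverage_end), "unparseable date")
    flag(!is.na(dt$coverage_start) & !is.na(dt$coverage_end) &
           dt$coverage_end < dt$coverage_start, "coverage_end < coverage_start")
    flag(!(dt$plan_type %in% PLAN_TYPES), "unknown plan_type")
    flag(!(dt$sex %in% SEX_LEVELS), "unknown sex")
    dt[, birth_year := suppressWarnings(as.integer(birth_year))]
    flag(is.na(dt$birth_year), "unparseable birth_year")
  } else if (table == "medical") {
    dt[, service_date := parse_iso_date(service_date)]
    flag(is.na(dt$service_date), "unparseable date")
    flag(is.na(dt$dx_codes) | dt$dx_codes == "", "empty dx_codes")
    flag(!(dt$place %in% PLACE_LEVELS), "unknown place")
    dt[, paid_total := suppressWarnings(as.numeric(paid_total))]
    flag(is.na(dt$paid_total) | dt$paid_total < 0, "negative or missing paid_total")
  } else {
    dt[, fill_date := parse_iso_date(fill_date)]
    flag(is.na(dt$fill_date), "unparseable date")
    flag(!(dt$drug_class %in% DRUG_CLASSES), "unknown drug_class")
    dt[, paid_total := suppressWarnings(as.numeric(paid_total))]
    flag(is.na(dt$paid_total) | dt$paid_total < 0, "negative or missing paid_total")
  }
  flag(is.na(dt$patient_id) | dt$patient_id == "", "missing patient_id")

  bad <- !is.na(reason)
  rejected <- data.table::data.table(row = which(bad), reason = reason[bad])
  list(kept = dt[!bad], rejected = rejected)
}

#' Validate a claims bundle
#'
#' Applies type and invariant checks row by row. Rows violating invariants are
#' dropped and recorded (with original row number and reason) in the `rejected`
#' attribute; a missing column raises a schema error naming the column.
#'
#' @param bundle A `claims_bundle`.
#' @return The validated bundle.
#' @export
validate_bundle <- function(bundle) {
  rej <- list()
  for (tb in names(BUNDLE_SCHEMAS)) {
    v <- validate_table(bundle[[tb]], tb)
    bundle[[tb]] <- v$kept
    rej[[tb]] <- v$rejected
  }
  attr(bundle, "rejected") <- rej
  bundle
}

#' Read a claims bundle from delimited-text files
#'
#' @param dir Directory holding `enrollment.csv`, `medical.csv`, `pharmacy.csv`
#'   (canonical dialect), or a named list/vector of three file paths with names
#'   `enrollment`, `medical`, `pharmacy`.
#' @param config A [study_config()] (kept for interface symmetry; validation
#'   does not depend on it).
#' @return A validated `claims_bundle`.
#' @export
read_bundle <- function(dir, config = study_config()) {
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    c(enrollment = file.path(dir, "enrollment.csv"),
      medical = file.path(dir, "medical.csv"),
      pharmacy = file.path(dir, "pharmacy.csv"))
  } else unlist(dir)
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tabs <- lapply(paths, data.table::fread,
                 colClasses = list(character = "patient_id"), keepLeadingZeros = TRUE)
  claims_bundle(tabs[["enrollment"]], tabs[["medical"]], tabs[["pharmacy"]])
}

#' Write a claims bundle in the canonical dialect
#'
#' UTF-8, comma-delimited, ISO-8601 dates, header row. `read_bundle()` of the
#' output reproduces the bundle (byte-stable round trip for validated bundles).
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(BUNDLE_SCHEMAS)) {
    out <- data.table::copy(bundle[[tb]])
    for (cl in names(out)) {
      if (inherits(out[[cl]], "Date")) data.table::set(out, j = cl, value = format(out[[cl]]))
    }
    data.table::fwrite(out, file.path(dir, paste0(tb, ".csv")), quote = FALSE)
  }
  invisible(dir)
}

#' Validation report for a bundle
#'
#' @param bundle A validated `claims_bundle`.
#' @return Character vector of report lines (also printed).
#' @export
validation_report <- function(bundle) {
  rej <- attr(bundle, "rejected")
  lines <- c(sprintf("patients: %d", length(unique(bundle$enrollment$patient_id))))
  for (tb in names(BUNDLE_SCHEMAS)) {
    lines <- c(lines, sprintf("%s: %d rows kept, %d rejected", tb,
                              nrow(bundle[[tb]]), if (is.null(rej)) 0L else nrow(rej[[tb]])))
    if (!is.null(rej) && nrow(rej[[tb]])) {
      tab <- table(rej[[tb]]$reason)
      lines <- c(lines, sprintf("  - %s: %d", names(tab), as.integer(tab)))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

# Merge overlapping/abutting coverage spans per patient (gap <= gap_days joins).
# Returns data.table(patient_id, coverage_start, coverage_end) sorted.
normalize_enrollment <- function(enrollment, gap_days = 0L) {
  en <- data.table::as.data.table(enrollment)[
    order(patient_id, coverage_start, coverage_end)]
  en[, grp := {
    s <- as.integer(coverage_start); e <- as.integer(coverage_end)
    g <- integer(.N); run_end <- e[1]
    if (.N > 1) for (i in 2:.N) {
      if (s[i] - run_end > gap_days + 1L) g[i] <- g[i - 1L] + 1L else g[i] <- g[i - 1L]
      run_end <- max(run_end, e[i])
    }
    g
  }, by = patient_id]
  out <- en[, .(coverage_start = min(coverage_start), coverage_end = max(coverage_end)),
            by = .(patient_id, grp)][, grp := NULL][]
  out
}

# TRUE iff patient's normalized coverage contains [from, to] entirely.
covers_interval <- function(norm_enroll, patient_id, from, to) {
  dt <- data.table::data.table(patient_id = patient_id, from = as.Date(from),
                               to = as.Date(to), row = seq_along(patient_id))
  m <- norm_enroll[dt, on = .(patient_id, coverage_start <= from, coverage_end >= to),
                   nomatch = NULL, mult = "first", .(row = i.row)]
  ok <- rep(FALSE, nrow(dt))
  ok[m$row] <- TRUE
  ok
}
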