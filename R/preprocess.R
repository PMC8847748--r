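#' Conversion-labeling rule
#'
#' A decline of `threshold_points` or more in the ADAS-cog score from the
#' reference visit defines clinically important cognitive improvement (CI);
#' anything less, or any increase, is cognition not improved (CNI).
#'
#' @param threshold_points Positive decline threshold in ADAS-cog points
#'   (default 4).
#' @param reference_month Visit month used as the reference (default 0,
#'   i.e. baseline; both follow-up labels are baseline-referenced).
#' @return An object of class `conversion_rule`.
#' @export
conversion_rule <- function(threshold_points = 4, reference_month = 0) {
  if (threshold_points <= 0) stopf("threshold_points must be > 0")
  structure(list(threshold_points = threshold_points,
                 reference_month = reference_month),
            class = "conversion_rule")
}

# Feature columns of a cohort table (excludes id/month/diagnosis).
table_features <- function(table, schema = NULL) {
  schema <- schema %||% attr(table, "schema")
  if (!is.null(schema)) {
    intersect(feature_names(schema), names(table))
  } else {
    setdiff(names(table), c("id", "month", "diagnosis"))
  }
}

is_categorical_col <- function(x) {
  if (!is.numeric(x)) return(TRUE)
  obs <- x[!is.na(x)]
  length(obs) > 0 && all(obs %in% c(0, 1))
}

#' Exclude sparsely observed features and patients
#'
#' Two-stage rule for "missing feature variables covering more than 50%":
#' first drop features observed in fewer than `feature_threshold` of patient
#' cells, then drop patients whose fraction of missing feature cells (static
#' cells counted once, time-dependent cells once per visit) strictly exceeds
#' `patient_threshold`. Both removals are recorded in the report.
#'
#' @param table A `cohort_table`.
#' @param patient_threshold Maximum tolerated per-patient missing fraction;
#'   strictly exceeding it excludes the patient. In (0, 1].
#' @param feature_threshold Minimum fraction of patients in which a feature
#'   must be observed to be retained.
#' @return A list with elements `table` and `report` (class
#'   `preprocess_report`).
#' @export
filter_missing <- function(table, patient_threshold = 0.5,
                           feature_threshold = 0.5) {
  if (patient_threshold <= 0 || patient_threshold > 1) {
    stopf("patient_threshold must be in (0,1]")
  }
  schema <- attr(table, "schema")
  feats <- table_features(table, schema)
  report <- list(dropped_features = character(0),
                 excluded_patients = data.frame(id = integer(0),
                                                missing_fraction = numeric(0)))
  if (nrow(table) == 0) {
    return(list(table = table,
                report = structure(report, class = "preprocess_report")))
  }

  statics <- if (!is.null(schema)) {
    intersect(static_feature_names(schema), feats)
  } else character(0)
  ids <- unique(table$id)

  # Per-feature observed fraction over patient cells.
  obs_frac <- vapply(feats, function(f) {
    if (f %in% statics) {
      one <- table[!duplicated(table$id), f]
      mean(!is.na(one))
    } else {
      mean(!is.na(table[[f]]))
    }
  }, numeric(1))
  drop_f <- feats[obs_frac < feature_threshold]
  if (length(drop_f)) {
    table <- table[, setdiff(names(table), drop_f), drop = FALSE]
    report$dropped_features <- drop_f
    feats <- setdiff(feats, drop_f)
    statics <- setdiff(statics, drop_f)
  }

  # Per-patient missing fraction: static cells once + time-dep cells per visit.
  tdep <- setdiff(feats, statics)
  frac <- vapply(ids, function(pid) {
    rows <- table[table$id == pid, , drop = FALSE]
    n_static_miss <- sum(is.na(rows[1, statics, drop = FALSE]))
    n_td_miss <- sum(is.na(rows[, tdep, drop = FALSE]))
    total <- length(statics) + length(tdep) * nrow(rows)
    (n_static_miss + n_td_miss) / total
  }, numeric(1))
  out_ids <- ids[frac > patient_threshold]
  if (length(out_ids)) {
    report$excluded_patients <- data.frame(
      id = out_ids, missing_fraction = frac[ids %in% out_ids])
    table <- table[!(table$id %in% out_ids), , drop = FALSE]
    rownames(table) <- NULL
  }
  list(table = table, report = structure(report, class = "preprocess_report"))
}

#' Impute missing cells with the feature mean or mode
#'
#' Continuous features receive the column mean of observed values; binary and
#' categorical features receive the mode, with ties broken by sorted order
#' (first value in ascending sort order wins), so imputation is deterministic.
#' Observed values are never touched.
#'
#' @param table A `cohort_table` (typically after [filter_missing()]).
#' @return A list with elements `table` (no missing feature cells remain) and
#'   `report` (the imputation value used per feature).
#' @export
impute_missing <- function(table) {
  feats <- table_features(table)
  values <- list()
  for (f in feats) {
    x <- table[[f]]
    if (!anyNA(x)) next
    obs <- x[!is.na(x)]
    if (length(obs) == 0) {
      stopf("feature '%s' has no observed values to impute from", f)
    }
    if (is_categorical_col(x)) {
      tab <- table(obs)
      best <- sort(names(tab)[tab == max(tab)])[1]
      fill <- if (is.numeric(x)) as.numeric(best) else best
    } else {
      fill <- mean(obs)
    }
    table[[f]][is.na(x)] <- fill
    values[[f]] <- fill
  }
  list(table = table,
       report = structure(list(imputation_values = values),
                          class = "preprocess_report"))
}

#' Standardize continuous features to zero mean and unit variance
#'
#' Means and standard deviations are estimated on the rows of `fit_ids` only
#' (the training patients), then applied to the whole table — the default
#' leakage-safe protocol for cross-validation. The population (divide by n)
#' standard deviation is used so the fitted rows have exactly unit variance.
#' Zero-variance features are mapped to 0 and flagged.
#'
#' @param table An imputed `cohort_table`.
#' @param fit_ids Patient ids on which to estimate the scaler; defaults to
#'   all patients.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list with elements `table` and `report` (per-feature mean/sd and
#'   any constant-feature flags).
#' @export
standardize_features <- function(table, fit_ids = unique(table$id),
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(fit_ids) == 0) stopf("fit_ids must be non-empty")
  if (!all(fit_ids %in% table$id)) {
    stopf("fit_ids must be a subset of the table's patient ids")
  }
  feats <- table_features(table)
  fit_rows <- table$id %in% fit_ids
  stats_tab <- list()
  constant <- character(0)
  for (f in feats) {
    x <- table[[f]]
    if (is_categorical_col(x)) next
    if (anyNA(x)) stopf("standardize_features requires an imputed table ('%s' has NA)", f)
    v <- x[fit_rows]
    m <- mean(v)
    s <- if (sd_type == "population") {
      sqrt(mean((v - m)^2))
    } else {
      stats::sd(v)
    }
    if (!is.finite(s) || s == 0) {
      table[[f]] <- rep(0, length(x))
      constant <- c(constant, f)
      stats_tab[[f]] <- list(mean = m, sd = 0)
    } else {
      table[[f]] <- (x - m) / s
      stats_tab[[f]] <- list(mean = m, sd = s)
    }
  }
  list(table = table,
       report = structure(list(standardization = stats_tab,
                               constant_features = constant),
                          class = "preprocess_report"))
}

#' Label cognitive conversion from ADAS-cog change
#'
#' For each follow-up month `t`, the label is CI when
#' `ADAS(reference) - ADAS(t) >= threshold_points` (a decline of exactly the
#' threshold counts as improved), else CNI. Patient-months whose follow-up
#' ADAS-cog is missing are omitted and listed in the `omitted` attribute.
#'
#' @param table A `cohort_table`; baseline ADAS-cog must be present for every
#'   labeled patient.
#' @param rule A [conversion_rule()].
#' @return A data.frame with columns `id`, `month`, `label` (factor CI/CNI),
#'   one row per patient per labelable follow-up month.
#' @export
label_conversion <- function(table, rule = conversion_rule()) {
  stopifnot(inherits(rule, "conversion_rule"))
  ref <- table[table$month == rule$reference_month, c("id", "adas_cog")]
  if (anyNA(ref$adas_cog)) {
    stopf("reference ADAS-cog missing for patient %s",
          ref$id[which(is.na(ref$adas_cog))[1]])
  }
  fup <- table[table$month != rule$reference_month, c("id", "month", "adas_cog")]
  fup$ref <- ref$adas_cog[match(fup$id, ref$id)]
  omitted <- fup[is.na(fup$adas_cog), c("id", "month")]
  fup <- fup[!is.na(fup$adas_cog), , drop = FALSE]
  decline <- fup$ref - fup$adas_cog
  out <- data.frame(
    id = fup$id, month = fup$month,
    label = factor(ifelse(decline >= rule$threshold_points, "CI", "CNI"),
                   levels = c("CNI", "CI"))
  )
  out <- out[order(out$id, out$month), ]
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
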