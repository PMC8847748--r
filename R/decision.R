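# Treatment-reassignment decision rule and actual-vs-predicted contingency
# analysis, overall and by stratum.

#' Flag patients for treatment reassignment
#'
#' A patient is flagged at a follow-up time point when their
#' (baseline-referenced) conversion label there is CNI: a decline of less
#' than the rule threshold, or any increase, marks the recommended treatment
#' as insufficient. The rule is applied identically to actual and to
#' model-predicted labels. With `cumulative = TRUE` a patient is instead
#' flagged once CNI at the given or any earlier follow-up (the
#' "either time point" reading).
#'
#' @param labels A label data.frame (`id`, `month`, `label`) — actual labels
#'   from [label_conversion()] or predicted labels in the same shape.
#' @param month Follow-up month to flag at.
#' @param cumulative Use the cumulative "CNI at any follow-up so far" reading.
#' @return A data.frame `id`, `month`, `flagged` (logical).
#' @export
flag_reassignment <- function(labels, month, cumulative = FALSE) {
  if (!month %in% labels$month) {
    stopf("no labels exist at month %s", month)
  }
  at <- labels[labels$month == month, , drop = FALSE]
  flagged <- at$label == "CNI"
  if (cumulative) {
    earlier <- labels[labels$month < month & labels$label == "CNI", "id"]
    flagged <- flagged | at$id %in% earlier
  }
  data.frame(id = at$id, month = month, flagged = as.logical(flagged))
}

#' Fraction of patients flagged for reassignment
#'
#' @param flags Output of [flag_reassignment()] (or any data.frame with a
#'   logical `flagged` column).
#' @return The flagged fraction in [0, 1].
#' @export
#' @examples
#' reassignment_rate(data.frame(flagged = rep(c(TRUE, FALSE), c(139, 85))))
reassignment_rate <- function(flags) {
  if (nrow(flags) == 0) stopf("no flags to summarize")
  mean(flags$flagged)
}

#' Pearson chi-square test on a 2x2 flagged/total comparison
#'
#' Uncorrected Pearson statistic on the table
#' `[[a, n1 - a], [b, n2 - b]]` with 1 degree of freedom.
#'
#' @param a,n1 Flagged count and total in the first group (e.g. actual).
#' @param b,n2 Flagged count and total in the second group (e.g. predicted).
#' @return A list of class `contingency_test`: `statistic`, `p_value`,
#'   `method = "pearson"`, and the counts.
#' @export
#' @examples
#' pearson_chi2_2x2(139, 224, 104, 224)$statistic  # 11.017
pearson_chi2_2x2 <- function(a, n1, b, n2) {
  check_2x2(a, n1, b, n2)
  O <- matrix(c(a, n1 - a, b, n2 - b), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  x2 <- sum((O - E)^2 / E)
  structure(list(statistic = x2, p_value = pchisq(x2, df = 1,
                                                  lower.tail = FALSE),
                 method = "pearson", a = a, n1 = n1, b = b, n2 = n2),
            class = "contingency_test")
}

#' Yates-corrected chi-square on a 2x2 table
#'
#' Offered as an alternative small-sample adjustment.
#' @inheritParams pearson_chi2_2x2
#' @return A `contingency_test` with `method = "yates"`.
#' @export
yates_chi2_2x2 <- function(a, n1, b, n2) {
  check_2x2(a, n1, b, n2)
  O <- matrix(c(a, n1 - a, b, n2 - b), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  x2 <- sum((pmax(abs(O - E) - 0.5, 0))^2 / E)
  structure(list(statistic = x2, p_value = pchisq(x2, 1, lower.tail = FALSE),
                 method = "yates", a = a, n1 = n1, b = b, n2 = n2),
            class = "contingency_test")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric point probabilities of
#' every table (with the same margins) no more probable than the observed one.
#'
#' @inheritParams pearson_chi2_2x2
#' @return A `contingency_test` with `method = "exact"` and `statistic = NA`
#'   (displayed as "-" in reports, as exact rows carry no chi-square value).
#' @export
exact_test_2x2 <- function(a, n1, b, n2) {
  check_2x2(a, n1, b, n2)
  m <- a + b            # total flagged
  support <- max(0, m - n2):min(m, n1)
  probs <- dhyper(support, n1, n2, m)
  p_obs <- dhyper(a, n1, n2, m)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(list(statistic = NA_real_, p_value = min(1, p),
                 method = "exact", a = a, n1 = n1, b = b, n2 = n2),
            class = "contingency_test")
}

check_2x2 <- function(a, n1, b, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("group totals must be positive")
  if (a > n1 || b > n2 || a < 0 || b < 0) {
    stopf("flagged counts must lie in [0, group total]")
  }
  invisible(TRUE)
}

# Choose pearson vs exact: exact when any expected cell count < 5.
min_expected_cell <- function(a, n1, b, n2) {
  O <- matrix(c(a, n1 - a, b, n2 - b), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  min(E)
}

compare_2x2 <- function(a, n1, b, n2, adjust = c("exact", "yates", "none")) {
  adjust <- match.arg(adjust)
  if (adjust != "none" && min_expected_cell(a, n1, b, n2) < 5) {
    if (adjust == "exact") exact_test_2x2(a, n1, b, n2)
    else yates_chi2_2x2(a, n1, b, n2)
  } else {
    pearson_chi2_2x2(a, n1, b, n2)
  }
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("2x2 %s test: %d/%d vs %d/%d, X2 = %s, p = %.3f\n",
              x$method, x$a, x$n1, x$b, x$n2,
              if (is.na(x$statistic)) "-" else sprintf("%.3f", x$statistic),
              x$p_value))
  invisible(x)
}

age_band <- function(age) {
  cut(age, breaks = c(50, 60, 70, 80, 90), right = FALSE,
      labels = c("50-59", "60-69", "70-79", "80-89"),
      include.lowest = TRUE)
}

#' Actual-vs-predicted treatment reassignment report
#'
#' Tabulates reassignment (CNI) fractions under the actual and the
#' model-predicted conversion labels at each follow-up, overall and within
#' strata (intervention arm, age band, gender, diagnosis class, and each
#' stratum crossed with arm), and tests each comparison with the uncorrected
#' Pearson chi-square, switching to Fisher's exact test whenever an expected
#' cell count is below 5 (statistic then reported as NA, printed "-").
#'
#' @param cohort A `cohort_table` carrying the stratifier columns (`arm`,
#'   `age`, `gender`, `diagnosis`).
#' @param actual Labels from [label_conversion()].
#' @param predicted Predicted labels in the same shape (e.g. from
#'   [predicted_labels()]); must cover the same patients.
#' @param months Follow-up months to report.
#' @param adjust Small-expected-count adjustment: `"exact"` (default),
#'   `"yates"`, or `"none"`.
#' @param cumulative Passed to [flag_reassignment()].
#' @return A data.frame of class `reassignment_table`: one row per stratum
#'   and time point with counts, percentages (2 decimals), statistic
#'   (3 decimals), p-value and method.
#' @export
reassignment_report <- function(cohort, actual, predicted, months = c(3, 6),
                                adjust = "exact", cumulative = FALSE) {
  base <- cohort[cohort$month == 0, , drop = FALSE]
  strata <- list(overall = rep("overall", nrow(base)))
  if ("arm" %in% names(base)) strata$arm <- base$arm
  if ("age" %in% names(base)) strata$age_band <- as.character(age_band(base$age))
  if ("gender" %in% names(base)) strata$gender <- base$gender
  if ("diagnosis" %in% names(base)) strata$diagnosis <- base$diagnosis
  if ("arm" %in% names(base)) {
    for (nm in intersect(c("age_band", "gender", "diagnosis"), names(strata))) {
      strata[[paste0(nm, ":arm")]] <- paste(strata[[nm]], base$arm, sep = ":")
    }
  }

  rows <- list()
  for (m in months) {
    fa <- flag_reassignment(actual, m, cumulative)
    fp <- flag_reassignment(predicted, m, cumulative)
    ids_m <- intersect(fa$id, fp$id)
    for (sname in names(strata)) {
      groups <- split(base$id, strata[[sname]])
      for (g in names(groups)) {
        gid <- intersect(groups[[g]], ids_m)
        n1 <- length(gid)
        if (n1 == 0) next
        a <- sum(fa$flagged[fa$id %in% gid])
        b <- sum(fp$flagged[fp$id %in% gid])
        if ((a == 0 && b == 0) || (a == n1 && b == n1)) {
          test <- list(statistic = NA_real_, p_value = NA_real_,
                       method = "degenerate")
        } else {
          test <- compare_2x2(a, n1, b, n1, adjust = adjust)
        }
        rows[[length(rows) + 1]] <- data.frame(
          stratifier = sname, stratum = g, month = m,
          actual_flagged = a, predicted_flagged = b, n = n1,
          actual_pct = round(100 * a / n1, 2),
          predicted_pct = round(100 * b / n1, 2),
          statistic = if (is.na(test$statistic)) NA_real_ else
            round(test$statistic, 3),
          p_value = test$p_value, method = test$method
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reassignment_table", "data.frame")
  out
}

#' McNemar's test for paired reassignment flags
#'
#' The actual and predicted flags describe the same patients, so the unpaired
#' chi-square of the published analysis is statistically questionable; this
#' explicitly labeled paired alternative tests the discordant pairs
#' (continuity-corrected).
#'
#' @param actual_flags,predicted_flags Logical vectors over the same patients
#'   in the same order.
#' @return A `contingency_test` with `method = "mcnemar"`.
#' @export
mcnemar_flags <- function(actual_flags, predicted_flags) {
  if (length(actual_flags) != length(predicted_flags)) {
    stopf("paired flag vectors must have equal length")
  }
  b <- sum(actual_flags & !predicted_flags)
  c_ <- sum(!actual_flags & predicted_flags)
  x2 <- if (b + c_ == 0) 0 else (abs(b - c_) - 1)^2 / (b + c_)
  structure(list(statistic = x2, p_value = pchisq(x2, 1, lower.tail = FALSE),
                 method = "mcnemar",
                 a = sum(actual_flags), n1 = length(actual_flags),
                 b = sum(predicted_flags), n2 = length(predicted_flags)),
            class = "contingency_test")
}

#' Convert model predictions into conversion labels
#'
#' Dichotomizes predicted probabilities at per-time-point thresholds
#' (default 0.5; typically the Youden-optimal cutoffs from cross-validation)
#' into the same `id`/`month`/`label` shape as [label_conversion()], so the
#' decision analysis treats actual and predicted conversion identically.
#'
#' @param predictions A data.frame `id`, `p3`, `p6` (e.g. the out-of-fold
#'   `predictions` of a `cv_result`).
#' @param thresholds Named numeric vector with entries `"3"` and `"6"`.
#' @return A label data.frame (`id`, `month`, `label`).
#' @export
predicted_labels <- function(predictions, thresholds = c("3" = 0.5, "6" = 0.5)) {
  out <- rbind(
    data.frame(id = predictions$id, month = 3,
               label = ifelse(predictions$p3 >= thresholds[["3"]], "CI", "CNI")),
    data.frame(id = predictions$id, month = 6,
               label = ifelse(predictions$p6 >= thresholds[["6"]], "CI", "CNI"))
  )
  out$label <- factor(out$label, levels = c("CNI", "CI"))
  out[order(out$id, out$month), ]
}
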