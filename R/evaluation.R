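# Cross-validated performance measurement: stratified folds, rank-based AUC,
# Youden-optimal cutoffs, exact binomial CIs, DeLong AUC CIs, and the
# mid-point withdrawal experiment.

#' Stratified k-fold assignment
#'
#' Shuffles each class separately and distributes members as evenly as
#' possible, placing per-class remainders on the currently smallest folds so
#' that overall fold sizes differ by at most one and per-fold class
#' proportions track the global ones.
#'
#' @param labels Class labels (any type coercible to factor).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical seed gives an identical assignment.
#' @return Integer vector of fold ids in `1:k`, one per observation.
#' @export
#' @examples
#' table(stratified_folds(rep(c("a", "b"), c(84, 140)), k = 5, seed = 1))
stratified_folds <- function(labels, k = 5, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  labels <- as.factor(labels)
  if (any(table(labels) < k)) {
    stopf("every class needs at least k members for stratified %d-fold assignment", k)
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    sizes <- integer(k)
    for (cl in levels(labels)) {
      ix <- sample(which(labels == cl))
      base <- length(ix) %/% k
      rem <- length(ix) %% k
      counts <- rep(base, k)
      if (rem > 0) {
        recipients <- order(sizes, seq_len(k))[seq_len(rem)]
        counts[recipients] <- counts[recipients] + 1L
      }
      fold[ix] <- rep(seq_len(k), counts)
      sizes <- sizes + counts
    }
    fold
  })
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels: 1/TRUE/"CI" marks the positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stopf("roc_auc requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    as.numeric(labels == "CI")
  } else {
    as.numeric(labels == 1 | labels == TRUE)
  }
}

#' Youden-optimal classification cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over all candidate thresholds
#' (midpoints between sorted unique scores, plus -Inf and +Inf); a prediction
#' is positive when its score is at or above the threshold. Ties in J are
#' broken by the lowest threshold, favoring sensitivity.
#'
#' @inheritParams roc_auc
#' @return A list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("youden_cutoff requires both classes")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (thr in cand) {
    pred <- as.numeric(scores >= thr)
    sens <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   youden_j = j)
    }
  }
  best
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

# DeLong variance of a single AUC, via placement values.
delong_auc_ci <- function(scores, labels, conf = 0.95) {
  y <- as_binary_labels(labels)
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
  v01 <- vapply(ys, function(yv) mean(psi(xs, yv)), numeric(1))
  auc <- mean(v10)
  s2 <- stats::var(v10) / m + stats::var(v01) / n
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(max(s2, 0))
  c(auc = auc, lower = max(0, auc - half), upper = min(1, auc + half))
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation: scores are swept from high to low
#' over unique thresholds and each recall increment contributes its precision
#' (average-precision style).
#'
#' @inheritParams roc_auc
#' @return AUPRC in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (sum(y) == 0) stopf("pr_auc requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # group ties so every threshold includes all equal scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a threshold
#'
#' Dichotomizes scores at `threshold` (positive when score >= threshold) and
#' reports accuracy, sensitivity, specificity, PPV and NPV with exact
#' Clopper-Pearson 95% intervals, the F-score (harmonic mean of PPV and
#' sensitivity), the AUC with a DeLong interval, and the AUPRC.
#'
#' @inheritParams roc_auc
#' @param threshold Finite classification threshold.
#' @param conf Confidence level for the intervals.
#' @return A one-row data.frame.
#' @export
confusion_metrics <- function(scores, labels, threshold, conf = 0.95) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  y <- as_binary_labels(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  n <- length(y)
  prop <- function(x, d) if (d == 0) NA_real_ else x / d
  ci <- function(x, d) {
    if (d == 0) return(c(NA_real_, NA_real_))
    clopper_pearson(x, d, conf)
  }
  acc <- prop(tp + tn, n); acc_ci <- ci(tp + tn, n)
  sens <- prop(tp, tp + fn); sens_ci <- ci(tp, tp + fn)
  spec <- prop(tn, tn + fp); spec_ci <- ci(tn, tn + fp)
  ppv <- prop(tp, tp + fp); ppv_ci <- ci(tp, tp + fp)
  npv <- prop(tn, tn + fn); npv_ci <- ci(tn, tn + fn)
  fsc <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) {
    NA_real_
  } else 2 * ppv * sens / (ppv + sens)
  au <- delong_auc_ci(scores, labels, conf)
  data.frame(
    n = n, tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold,
    accuracy = acc, accuracy_lo = acc_ci[1], accuracy_hi = acc_ci[2],
    sensitivity = sens, sensitivity_lo = sens_ci[1], sensitivity_hi = sens_ci[2],
    specificity = spec, specificity_lo = spec_ci[1], specificity_hi = spec_ci[2],
    ppv = ppv, ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2],
    npv = npv, npv_lo = npv_ci[1], npv_hi = npv_ci[2],
    f_score = fsc,
    auc = unname(au["auc"]), auc_lo = unname(au["lower"]),
    auc_hi = unname(au["upper"]),
    auprc = pr_auc(scores, labels)
  )
}

#' Aggregate per-fold AUCs into a mean and normal-approximation CI
#'
#' @param aucs Numeric vector of per-fold AUCs (length >= 2).
#' @param conf Confidence level.
#' @return A list with `mean`, `lower`, `upper`.
#' @export
#' @examples
#' aggregate_folds(c(0.737, 0.754, 0.761, 0.758, 0.670))
aggregate_folds <- function(aucs, conf = 0.95) {
  if (length(aucs) < 2) stopf("need at least 2 folds to aggregate")
  z <- qnorm(1 - (1 - conf) / 2)
  m <- mean(aucs)
  se <- stats::sd(aucs) / sqrt(length(aucs))
  list(mean = m, lower = m - z * se, upper = m + z * se)
}

#' Cross-validated training and evaluation
#'
#' Splits patients into stratified folds on the 6-month conversion label,
#' and for each fold: standardizes continuous features on the training
#' patients only (or on everyone with `paper_faithful = TRUE`, reproducing
#' whole-dataset normalization), trains the hybrid model, predicts the held
#' out fold, picks the Youden-optimal cutoff per time point on the held-out
#' scores, and computes the full metric row.
#'
#' @param table An imputed (not yet standardized) `cohort_table`.
#' @param labels Conversion labels from [label_conversion()]; patients
#'   lacking either follow-up label are dropped from CV.
#' @param k Number of folds.
#' @param train_cfg A [training_config()] applied to every fold (per-fold
#'   seeds are derived from it).
#' @param seed Seed for the fold assignment.
#' @param paper_faithful Standardize on the whole dataset before splitting
#'   instead of per training fold.
#' @return An object of class `cv_result`: per-fold `metrics` (rows for 3 and
#'   6 months), `predictions` (out-of-fold scores per patient), `models`,
#'   `fold_assignment`, and `summary` (mean AUC with CI per time point).
#' @export
cross_validate <- function(table, labels, k = 5,
                           train_cfg = training_config(),
                           seed = 1L, paper_faithful = FALSE) {
  lab3 <- labels[labels$month == 3, ]
  lab6 <- labels[labels$month == 6, ]
  ids <- intersect(lab3$id, lab6$id)
  ids <- ids[order(ids)]
  table <- table[table$id %in% ids, , drop = FALSE]
  y6 <- lab6$label[match(ids, lab6$id)]
  fold <- stratified_folds(y6, k = k, seed = seed)

  if (paper_faithful) {
    table <- standardize_features(table)$table
  }

  metrics <- list()
  preds <- list()
  models <- list()
  for (f in seq_len(k)) {
    test_ids <- ids[fold == f]
    train_ids <- setdiff(ids, test_ids)
    std <- if (paper_faithful) {
      list(table = table)
    } else {
      standardize_features(table, fit_ids = train_ids)
    }
    tr_tab <- std$table[std$table$id %in% train_ids, , drop = FALSE]
    te_tab <- std$table[std$table$id %in% test_ids, , drop = FALSE]
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    mod <- train_conversion_model(tr_tab, labels, train_cfg = cfg_f)
    pr <- predict(mod, te_tab, labels3 = labels)
    pr$fold <- f
    pr$y3 <- as_binary_labels(lab3$label[match(pr$id, lab3$id)])
    pr$y6 <- as_binary_labels(lab6$label[match(pr$id, lab6$id)])
    preds[[f]] <- pr
    models[[f]] <- mod
    for (tp in c(3, 6)) {
      sc <- if (tp == 3) pr$p3 else pr$p6
      yy <- if (tp == 3) pr$y3 else pr$y6
      cut <- youden_cutoff(sc, yy)
      # an infinite optimum means classify-everything one way; use the
      # equivalent finite threshold for the metric row
      thr <- if (cut$threshold == -Inf) {
        min(sc)
      } else if (cut$threshold == Inf) {
        max(sc) + 1
      } else cut$threshold
      row <- confusion_metrics(sc, yy, thr)
      row <- cbind(data.frame(fold = f, month = tp,
                              youden_j = cut$youden_j), row)
      metrics[[length(metrics) + 1]] <- row
    }
  }
  metrics <- do.call(rbind, metrics)
  preds <- do.call(rbind, preds)
  summary <- do.call(rbind, lapply(c(3, 6), function(tp) {
    ag <- aggregate_folds(metrics$auc[metrics$month == tp])
    data.frame(month = tp, mean_auc = ag$mean, auc_lower = ag$lower,
               auc_upper = ag$upper,
               mean_accuracy = mean(metrics$accuracy[metrics$month == tp]))
  }))
  structure(list(metrics = metrics, predictions = preds, models = models,
                 fold_assignment = data.frame(id = ids, fold = fold),
                 summary = summary, paper_faithful = paper_faithful),
            class = "cv_result")
}

#' Mid-point withdrawal experiment
#'
#' Re-evaluates each fold's already-trained model with the 3-month visit
#' removed from the input sequence (no retraining), emulating a missed
#' follow-up, and reports the paired 6-month AUCs.
#'
#' @param cv A `cv_result` from [cross_validate()].
#' @param table The same imputed `cohort_table` used for cross-validation.
#' @param zero_fill Zero-fill the withdrawn step instead of removing it.
#' @return A data.frame with one row per fold: `auc_full`, `auc_withdrawn`,
#'   `auc_diff`, plus a `summary` attribute with the mean AUCs.
#' @export
withdrawal_experiment <- function(cv, table, zero_fill = FALSE) {
  ids <- cv$fold_assignment$id
  table <- table[table$id %in% ids, , drop = FALSE]
  out <- lapply(seq_along(cv$models), function(f) {
    test_ids <- ids[cv$fold_assignment$fold == f]
    train_ids <- setdiff(ids, test_ids)
    std <- if (cv$paper_faithful) {
      standardize_features(table)
    } else {
      standardize_features(table, fit_ids = train_ids)
    }
    te_tab <- std$table[std$table$id %in% test_ids, , drop = FALSE]
    pr_w <- predict(cv$models[[f]], te_tab, withdraw_mid = TRUE,
                    zero_fill = zero_fill)
    prev <- cv$predictions[cv$predictions$fold == f, ]
    y6 <- prev$y6[match(pr_w$id, prev$id)]
    auc_full <- roc_auc(prev$p6[match(pr_w$id, prev$id)], y6)
    auc_w <- roc_auc(pr_w$p6, y6)
    data.frame(fold = f, auc_full = auc_full, auc_withdrawn = auc_w,
               auc_diff = auc_full - auc_w)
  })
  out <- do.call(rbind, out)
  attr(out, "summary") <- c(mean_full = mean(out$auc_full),
                            mean_withdrawn = mean(out$auc_withdrawn))
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
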