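#!/usr/bin/env Rscript
# Train and evaluate the hybrid static-encoder + LSTM + attention model with
# stratified five-fold cross-validation. Scalers are fitted per training
# fold; the Youden-optimal cutoff on the held-out scores dichotomizes each
# fold's predictions. Writes the per-fold metric table, the out-of-fold
# predictions, and one JSON weight checkpoint per fold. Takes a few minutes.

library(cogconvert)

imp <- read_cohort("results/cohort_imputed.csv")
labels <- read.csv("results/labels.csv")
labels$label <- factor(labels$label, levels = c("CNI", "CI"))

cv <- cross_validate(imp, labels, k = 5,
                     train_cfg = training_config(seed = 20260918),
                     seed = 20260918)

write.csv(cv$metrics, "results/cv_metrics.csv", row.names = FALSE)
write.csv(cv$predictions, "results/cv_predictions.csv", row.names = FALSE)
write.csv(cv$fold_assignment, "results/fold_assignment.csv", row.names = FALSE)
dir.create("results/models", showWarnings = FALSE)
for (f in seq_along(cv$models)) {
  save_model(cv$models[[f]], sprintf("results/models/fold_%d.json", f))
}

cat("Cross-validated performance (mean AUC with normal-approximation CI):\n")
print(cv$summary, row.names = FALSE)
cat("\nPer-fold AUCs:\n")
print(cv$metrics[, c("fold", "month", "accuracy", "sensitivity",
                     "specificity", "auc", "auprc")], row.names = FALSE)
cat("Wrote results/cv_metrics.csv, results/cv_predictions.csv, checkpoints\n")
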