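# cogconvert

Longitudinal prediction of cognitive conversion in AD/MCI, and the
treatment-reassignment decision analysis built on it.

Patients with Alzheimer's disease or mild cognitive impairment are assessed
with the ADAS-cog (0–70, higher = worse) at months 0, 3 and 6. A decline of
**≥ 4 points from baseline** labels a follow-up *cognition improved* (CI);
anything less, or any increase, is *cognition not improved* (CNI), and a CNI
patient is flagged as needing upgraded or redirected treatment. The package
implements:

* a **synthetic cohort simulator** emulating a published 224-patient
  AD/MCI cohort (five intervention arms, arm-dependent ADAS-cog drifts,
  AR(1) visit noise, coupled secondary scales, controllable missingness),
  so every stage is testable without the private study data;
* the **preprocessing rules**: >50% missingness exclusion (feature- and
  patient-wise), mean/mode imputation, z-scoring with population sd fitted
  leakage-safely per training fold;
* the **hybrid model**: a five-layer fully connected ReLU encoder compresses
  static features to a logistic score `s`, which is fused with the visit-level
  scales and the previous-step conversion status into an LSTM; scaled
  dot-product attention `softmax(QKᵀ/√d)·V` over the hidden states feeds
  per-horizon logistic heads. Training: Adam (lr 0.01, ×0.1 at epochs
  400/800), 1000 epochs, full batch, teacher forcing, summed per-step binary
  cross-entropy, group-lasso on input weight rows, epoch selected by highest
  6-month validation AUC across 2 restarts. Forward and backward passes are
  hand-written base-R matrix code, gradient-checked against numerical
  differentiation;
* **evaluation**: stratified 5-fold cross-validation; Mann–Whitney AUC;
  Youden-optimal cutoffs (J = sensitivity + specificity − 1); accuracy /
  sensitivity / specificity / PPV / NPV with exact Clopper–Pearson 95% CIs;
  DeLong AUC intervals; step-wise AUPRC; mean-AUC aggregation (±1.96·SE);
* the **withdrawal ablation**: re-evaluating a trained model with the
  3-month visit removed from its inputs (no retraining), emulating a missed
  follow-up;
* the **decision analysis**: actual vs predicted reassignment fractions per
  stratum, compared with the uncorrected Pearson chi-square (Fisher's exact
  when an expected cell < 5; McNemar available as the paired alternative).

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # cohort CSV + schema sidecar
Rscript analysis/02_preprocess.R          # filtering, labels, imputation
Rscript analysis/03_train_crossvalidate.R # 5-fold CV + JSON checkpoints
Rscript analysis/04_withdrawal.R          # mid-point withdrawal ablation
Rscript analysis/05_decision.R            # reassignment contingency table
```

Output of one full run (seed 20260918):

```
Simulated 224 patients (131 AD, 93 MCI)
Age 69.50 (8.38); baseline ADAS-cog 17.15 (9.41); 63.3% female
Month 3: 71 CI / 140 CNI (CI prevalence 33.6%)

Cross-validated performance (mean AUC with normal-approximation CI):
 month  mean_auc auc_lower auc_upper mean_accuracy
     3 0.5601319 0.4387176 0.6815462     0.6056410
     6 0.7521025 0.6748303 0.8293747     0.7580769

Mean full 0.752 -> mean withdrawn 0.535 (drop 0.217)

Month 3: actual 131/198 (66.16%) vs predicted 64/198 (32.32%), X2 = 45.354, p = 0.000
Month 6: actual 91/198 (45.96%) vs predicted 83/198 (41.92%), X2 = 0.656, p = 0.418
```

Reading: the model discriminates 6-month conversion (AUC 0.75) far better
than 3-month conversion (where only the treatment arm carries signal at
baseline); withdrawing the 3-month visit from the trained model costs 0.22
AUC, quantifying the value of the mid-point follow-up; and the predicted
6-month reassignment fraction is statistically indistinguishable from the
actual one (p = 0.42), while at 3 months the weak predictor under-flags.

In code, the same pipeline is one call:

```r
library(cogconvert)
res <- run_pipeline(list(seed = 1, n_patients = 224))
res$cv$summary          # per-horizon cross-validated summary
res$withdrawal          # per-fold withdrawal ablation
res$reassignment        # stratified actual-vs-predicted contingency table
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
simulates a cohort, preprocesses and labels it, trains and cross-validates
the hybrid model, runs the withdrawal ablation and the reassignment
analysis — prints the headline numbers, and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                  package code (simulator, preprocess, model, evaluation,
                    decision, pipeline)
analysis/           numbered narrative drivers (see above)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/cognitive-conversion-methods.Rmd   methods notes
```
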