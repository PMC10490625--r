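# eegactivity

Classifying everyday human activities — resting, reading, walking,
working — from six-channel scalp EEG (Fz, C1, C2, T7, T8, Oz), and
explaining each prediction in terms of the spectral features that drove
it. The package is aimed at biomedical-signal researchers who want a
fully tested, reproducible reference pipeline for EEG-based human
activity recognition: synthetic data with known ground truth,
preprocessing, spectral features, ensemble classifiers, standard
evaluation metrics, and a from-scratch local-surrogate explainer.

## What it computes

**Features** (per 10-s epoch, per region F/C/T/O and global G):

- Relative band power, for band *j* within a region:
  `RP_j = P_j / Σ_j P_j`, with band powers integrated from a Welch
  periodogram (2-s Hamming segments, 10% overlap) over delta 0.5–4,
  theta 4–8, alpha 8–13, beta 13–30 and gamma 30–44 Hz.
- Pairwise-derived brain symmetry index over homologous pairs
  (C2, C1) and (T8, T7):
  `pdBSI = (1/pq) Σ_i Σ_j |Rt_ij − Lt_ij| / (Rt_ij + Lt_ij)`,
  0 = perfect symmetry, 1 = total asymmetry.
- Spectral ratios DAR = delta/alpha, DTR = delta/theta,
  DTABR = (delta+theta)/(alpha+beta).

**Preprocessing**: 60 Hz band-stop → FastICA artifact removal against
EOG/EMG reference channels (components with |r| > 0.7 zeroed) →
SNR-based epoch rejection (epochs below 25 dB discarded, where
SNR = 10·log₁₀ of in-band over out-of-band power) → 0.5–44 Hz band-pass.

**Models**: ANOVA-F top-20 feature selection (fitted on the training
partition only), stratified 80/20 split, random forest / gradient
boosting / extreme gradient boosting with stratified 10-fold CV tuning
over tree count × depth.

**Evaluation**: confusion matrix; per-class precision TP/(TP+FP), recall
TP/(TP+FN), F1 = 2PR/(P+R), overall accuracy, support-weighted averages;
one-vs-rest ROC with trapezoid AUC (equal to the normalized Mann–Whitney
U statistic, ties counted half).

**Explanations**: a tabular local surrogate in the LIME family — Gaussian
perturbations scaled by training spreads, proximity kernel
exp(−D²/w²) with w = 0.75·√d, weighted ridge fit of the class
probability, hard top-K sparsification and refit — yielding signed
per-feature contributions with a weighted-R² fidelity diagnostic.

## Worked example

```r
library(eegactivity)

cfg <- simulation_config(
  epochs_per_activity = c(reading = 40, walking = 40, working = 40,
                          resting = 40),
  seed = 42)
rec <- generate_recording(cfg)
rec
#> <raw_recording> 8 channels x 400000 samples @ 250 Hz (1600.0 s)
#>  channels: Fz, C1, C2, T7, T8, Oz, EOG, EMG
#>  annotations: reading=40, resting=40, walking=40, working=40

epochs   <- preprocess_recording(rec)
#> [ica] removing 2/6 components (|r| > 0.70)
#> [snr] kept 160, rejected 0 of 160 epochs (threshold 25 dB)
features <- build_feature_table(epochs)

split  <- split_train_test(features, test_fraction = 0.2, seed = 1)
scores <- score_features(split$train)
train  <- select_top_k(split$train, scores, k = 20)
test   <- split$test[, c(attr(train, "selected"), "label")]

model  <- train_model(train, model_spec("random_forest",
                                        n_estimators = 98,
                                        max_depth = 21, seed = 1))
report <- evaluate_model(model, test)
cat(format_eval_table(report), sep = "\n")
#> Accuracy = 100.00%
#> Activity Class     Precision    Recall  F1-Score
#> reading                 1.00      1.00      1.00
#> resting                 1.00      1.00      1.00
#> walking                 1.00      1.00      1.00
#> working                 1.00      1.00      1.00
#> Weighted Average        1.00      1.00      1.00

idx <- which(test$label == "working")[1]
explain_instance(model, test[idx, ], lime_config(seed = 1))
#> <explanation> predicted working (p = 0.59); surrogate R2 = 0.506
#>    -0.0644  DTABR_C > 1.05
#>    +0.0614  RP_Gamma_C > 0.123
#>    +0.0606  RP_Gamma_F > 0.121
#>    -0.0214  DTABR_F > 1.05
#>    +0.0164  RP_Gamma_G > 0.0891
#>    ...
```

The ICA log line shows the blink and muscle components being removed; no
epochs are rejected because this configuration injects no motion
corruption. The perfect held-out accuracy is a property of the
well-separated synthetic profiles, not a claim about field recordings.
In the explanation, positive weights (elevated central/frontal gamma,
`RP_Gamma_C`, `RP_Gamma_F`) push the prediction toward "working"; the
condition after each weight locates the instance's value relative to the
training quartiles. The `simulation_config()` defaults reproduce the
study-scale composition (793/408/267/243 epochs); `run_pipeline()`
orchestrates all stages end-to-end into a run directory with a
reconciling provenance manifest.

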