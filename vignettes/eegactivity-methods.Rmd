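---
title: "Recognizing everyday activities from EEG spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing everyday activities from EEG spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Scalp EEG reflects the brain's functional state, and the balance of power
across the classical frequency bands — delta (0.5–4 Hz), theta (4–8 Hz),
alpha (8–13 Hz), beta (13–30 Hz) and gamma (30–44 Hz) — shifts with
cognitive and motor load. `eegactivity` implements a complete, testable
pipeline that classifies four everyday activity states (resting, reading,
walking, working) from six EEG channels (Fz, C1, C2, T7, T8, Oz), and then
explains individual predictions in terms of the spectral features that
drove them. Because no public recording set accompanies this analysis
design, the package ships a first-class synthetic-EEG module with known
ground truth, so every downstream stage is tested against quantities that
are exactly known by construction.

## Preprocessing

The cleaning chain runs in a fixed, logged order:

1. **60 Hz band-stop** (Butterworth, order 4, applied forward–backward so
   the filter is zero-phase and epoch timing is untouched) removes mains
   contamination.
2. **ICA artifact removal.** The six EEG channels are decomposed with
   FastICA (tanh contrast, symmetric decorrelation, whitening by
   eigendecomposition; the unmixing matrix is estimated on a column
   subsample for speed and applied to the full recording). Any independent
   component whose absolute Pearson correlation with a reference channel
   (EOG, EMG) exceeds 0.7 is zeroed before remixing. With no reference
   channels the step is a warned no-op — automatic component
   classification is out of scope.
3. **Segmentation** into non-overlapping 10-s epochs aligned to the
   activity annotations; a trailing remainder shorter than one epoch is
   dropped rather than padded (no fabricated samples).
4. **SNR-based epoch rejection.** Per epoch,
   SNR(dB) = 10·log₁₀(P_in / P_out), with P_in the mean per-channel power
   in 0.5–44 Hz and P_out the mean power from 44 Hz to Nyquist, computed
   on the signal before any band-pass. Epochs below 25 dB are rejected.
   This estimator is a declared choice: it is computable from the signal
   alone and strictly decreasing in injected broadband noise, which is
   exactly what motion corruption adds. An epoch with no out-of-band
   energy has infinite SNR and is kept.
5. **0.5–44 Hz band-pass** of the kept epochs. This stage uses an ideal
   zero-phase frequency-domain filter (out-of-band DFT bins zeroed). An
   IIR band-pass necessarily attenuates the upper gamma band below its
   44 Hz corner (roughly a quarter of 30–44 Hz power at order 4, even
   applied forward–backward), which would bias gamma relative power by
   more than the pipeline's own recovery tolerance; the ideal filter has
   unit passband gain by construction. The general-purpose
   `apply_filter()` retains the Butterworth family for the notch and for
   users who want conventional IIR behaviour.

The order — notch, ICA, rejection, band-pass — matters: ICA must see (and
remove) muscle bursts before the SNR screen, otherwise every epoch
containing a burst would be discarded along with the genuinely
motion-corrupted ones, and the SNR screen must see out-of-band energy
before the band-pass erases it.

## Spectral features

Per kept epoch, power spectral densities are estimated with Welch's
averaged modified periodogram: 2-s Hamming-tapered segments with 10%
overlap, giving 0.5 Hz resolution — the coarsest grid that still resolves
the 0.5 Hz delta edge. Scaling is such that the one-sided PSD integrates
to the signal variance (Parseval), which the tests verify with closed-form
sinusoid and white-noise oracles. The 49 features are:

- **Relative band power** `RP_<Band>_<Region>`: band power (trapezoid over
  the Welch grid) divided by total 0.5–44 Hz power, per region
  F (= Fz), C (= mean of C1, C2), T (= mean of T7, T8), O (= Oz) and
  G (= mean of all six channels; RP only). Shared band edges belong to the
  upper band, and because trapezoids over contiguous intervals add
  exactly, each region's five fractions sum to 1 to machine precision.
- **Pairwise-derived brain symmetry index** `pdBSI_<Band>_<C|T>` and
  broadband `pdBSI_<C|T>`: the mean over frequency bins of
  |R − L| / (R + L) for the homologous pairs (C2, C1) and (T8, T7);
  0 means perfect symmetry, 1 total asymmetry. Bins with R + L = 0 are
  skipped with the bin count reduced; an all-zero band yields a missing
  value.
- **Power ratios** `DAR_<Region>` (delta/alpha), `DTR_<Region>`
  (delta/theta), `DTABR_<Region>` ((delta+theta)/(alpha+beta)) for
  F, C, T, O. Zero denominators yield missing values, never infinities;
  rows with any missing mandatory feature are dropped with a logged count.

## Feature selection, models, evaluation

Features are scored by the one-way ANOVA F statistic across the four
activity labels (between-group over within-group mean squares, computed
from the definition and cross-checked against `anova(lm(...))` in the
tests); the top 20 enter the classifiers. Selection is fitted on the
training partition only — the test suite plants a feature that is
predictive only in the held-out partition and verifies it cannot be
selected.

Three ensemble families are supported: random forest (via `ranger`),
gradient boosting and extreme gradient boosting (both via `xgboost`; the
plain variant runs with the classical 0.1 learning rate and no
regularization, the extreme variant keeps the library's regularized
defaults). Tuning maximizes mean stratified 10-fold cross-validated
accuracy over a grid of tree count × depth spanning the canonical ranges
(1–100 × 1–30 for the forest and extreme boosting, 1–50 × 1–14 for plain
boosting), thinned by a configurable stride; each family's reference
operating point (98/21, 50/8, 83/10) is always in the grid, and ties go to
the smaller model. The 80/20 split is stratified by activity and
deterministic under its seed.

Evaluation produces the confusion matrix; per-class one-vs-rest precision,
recall and F1 with support-weighted averages; overall accuracy as the
diagonal total over all instances (the standard multiclass reading — the
binary TP/TN form is recovered in the two-class case); and one-vs-rest ROC
curves with trapezoid AUC. The trapezoid AUC equals the Mann–Whitney U
statistic normalized by positives × negatives with ties counted half — an
identity the tests assert to 1e-9 on tied score sets. Cross-validated ROC
curves pool out-of-fold probabilities via `cv_probabilities()`.

## The local surrogate explainer

For a single instance, the explainer draws `n_samples` (default 5000)
perturbations, each feature from a normal law centered on the instance
value with the training-set standard deviation (features with zero spread
stay fixed); weighs each sample by exp(−D²/w²), where D is the Euclidean
distance to the instance in standardized units and the kernel width w
defaults to 0.75·√d; fits a proximity-weighted ridge regression of the
black box's class probability on all standardized features; keeps the K
(default 10) largest absolute standardized coefficients; and refits the
weighted ridge on the kept set. The result is a sparse local linear model
minimizing the proximity-weighted loss under a hard K-feature complexity
constraint, reported with its weighted R² as a fidelity diagnostic.

Design choices: features are perturbed continuously without
discretization, because every feature here is a continuous spectral
quantity; training quartiles are used only to render the display condition
next to each contribution (e.g. `RP_Gamma_C > q3`). The surrogate
regresses the probability, not the log-odds, so contribution weights live
on the probability scale. A constant black box yields zero coefficients,
the constant as intercept, and an undefined (NA) R². Contribution weights
are reported in standardized-coefficient units; any percentage view is a
display normalization, not a model quantity.

Two properties worth knowing before reading explanations: the linear
surrogate's coefficients vanish near an *interior* class's probability
peak (the surface is locally quadratic there), so explanations are
sharpest for instances the model places on the extremes of a feature
gradient; and correlated features share attribution, because the forest
spreads its splits across them.

## The synthetic-EEG generator

Each activity has a profile: for each region, the fraction of power per
band, plus an RMS amplitude. Within every 10-s epoch, each channel is a
sum of five band-limited Gaussian components synthesized in the frequency
domain — Gaussian Fourier coefficients confined to the band, i.e. white
noise through an ideal zero-phase band-pass — and scaled so the epoch
attains its region's target fractions exactly at DFT resolution. This
choice (over IIR-filtered noise) keeps clean epochs free of out-of-band
leakage, which matters twice: leakage would bias gamma recovery, and it
would park clean epochs near the 25 dB rejection threshold.

Homologous channels (C1/C2, T7/T8) share 90% of each band component's
variance, emulating a common cortical source seen by both electrodes, so
the symmetry index of artifact-free data stays low (the finite-sample
floor of |R−L|/(R+L) for independent spectra would otherwise sit near
0.24 at five Welch segments — a purely statistical offset, not
asymmetry); an `asymmetry` parameter scales the right-side variance to
create known asymmetry for tests. Per-region amplitude multipliers
(O 1.4 > F = T 1.2 > C 0.4) mimic typical scalp topography — and ensure
the global-average region G is not just a low-noise copy of any single
region's signal.

The four default profiles are well-separated by design and echo the
qualitative contrasts the analysis is meant to detect: resting carries
high (especially occipital) alpha; reading lowers frontal alpha and
central beta/gamma; walking raises frontal theta, occipital alpha and
central beta; working is defined by strongly elevated central gamma
(0.32 vs ≤ 0.08 elsewhere) with the rest of its spectrum close to
resting — so central gamma is the defining signature, which is exactly the
condition under which the explainer is expected to surface `RP_Gamma_C`.

Artifacts: a 60 Hz mains sinusoid on every channel; blink-like
raised-cosine transients (300 µV, 12/min) mixed most strongly into Fz and
doubled on the EOG reference; one-sided temporal muscle bursts (30–100 Hz,
350 µV, 10/min) into T7 (weakly T8) and doubled on the EMG reference; and,
in a configurable fraction of epochs, broadband motion noise at twice the
signal RMS, which drives the epoch's SNR to ≈ 0 dB, far below the 25 dB
threshold. Artifact amplitudes are set where real blinks and jaw-muscle
bursts live — large relative to background EEG — which is also the regime
in which a reference-correlation rule at |r| > 0.7 reliably flags the
corresponding components; a correlation rule cannot beat the ratio of
artifact to background variance in the artifact's spatial direction, so
faint artifacts are intrinsically undetectable by it.

The default composition is 793 reading, 408 walking, 267 working and 243
resting epochs — the study-scale feature dataset — with
`motion_epoch_fraction = 0`, since that composition describes data that
already passed rejection; motion corruption is switched on explicitly
where rejection behaviour is under test.

What the generator does **not** emulate: 1/f spectral shape, sleep
spindles or other transient morphology, nonstationarity within an
activity block, inter-subject variability, volume-conduction mixing
between regions, or electrode drift. Passing tests therefore demonstrate
that the pipeline recovers what it is designed to measure under its own
assumptions — not that real EEG of these activities is this separable.
The held-out accuracy near 1.0 on the defaults is a property of the
synthetic design, deliberately stronger than any field recording would
allow.

## Numerical choices and degenerate inputs

- Welch segments are demeaned per segment; the one-sided PSD doubles all
  bins except DC and Nyquist.
- Band-power integration interpolates linearly at band edges when the
  grid does not land on them (with the default 0.5 Hz grid it always
  does).
- "10 percent Hamming window" is realized as a Hamming taper with 10%
  inter-segment overlap and a 2-s segment; segment length is a free
  parameter the source analysis leaves open, fixed here for delta-edge
  resolution.
- Ridge systems in the explainer are solved in closed form; a singular
  system raises the penalty a documented hundredfold once and retries.
- Stratified splits round the per-class test count to the nearest
  integer, so proportions hold within one instance per class.
- Ties in feature selection break by fixed column order; ties in tuning
  go to fewer trees, then shallower.
- One global seed expands into fixed per-stage offsets (simulate, ICA,
  split, tune, train, explain), so each stage is independently
  reproducible.

## Problem sizes used by the test suite

The acceptance-style tests run the full study-scale composition (1711
epochs, ≈ 4.3 M samples across 8 channels) once and share it; parameter
recovery uses 32 artifact-free epochs per activity (the averaging the
recovery tolerance is stated for); unit tests use 1–15 epochs per
activity. Tuning in tests uses the strided default grid (25 specs), a
deliberate desk-scale setting of the same machinery that runs the full
ranges.

## Known limitations

- The SNR estimator is a spectral proxy; it cannot flag artifacts that
  live entirely inside 0.5–44 Hz (blinks are handled by ICA instead).
- Reference-free artifact removal is out of scope; without EOG/EMG
  channels the ICA stage passes data through.
- The EDF writer/reader covers the package's own output (EDF+C, 16-bit,
  whole-second records), not the format's full generality.
- Explanations inherit LIME's known instabilities: attribution splits
  across correlated features and weakens at interior-class probability
  peaks; the reported weighted R² should gate any substantive reading of
  an explanation.
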