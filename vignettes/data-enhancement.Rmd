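---
title: "Data enhancement for ultrasound lesion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data enhancement for ultrasound lesion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sonoclean)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The workflow and its unit of analysis

The package targets multiclass lesion classification from 2-D ultrasound
images where each *patient* contributes several images (typically one or
more per acquisition view) and carries one pathology-confirmed diagnosis.
Every consequential operation therefore treats the patient, not the
image, as the atomic unit:

* the train/test split samples **patients** within each class, so no
  patient's images straddle the split;
* the out-of-fold machinery groups folds by **patient**;
* at evaluation, all image probability rows of one patient are averaged
  before the argmax, and all metrics count **patients**.

Image-level splitting would leak near-duplicate frames of one patient
across the boundary and inflate every metric; the access audit
(`audit_images()`, `audit_log()`) exists so tests can *prove* the test
split is untouched until prediction.

### Split arithmetic

Within each class, `round_half_away(test_fraction * n_patients)` patients
go to the test set. The rounding rule is round-half-away-from-zero; with
a 30% fraction and class patient counts (168, 290, 276) it yields test
counts (50, 87, 83) — totals 220 test and 514 training patients — which
is the arithmetic the package's acceptance checks pin down. Plain
`round()` (banker's rounding) would disagree on exact halves.

## Stage 1 — out-of-fold features and consensus cleaning

**Why out-of-fold.** Anomaly scores computed from a representation that
was fit on the scored images themselves are biased toward calling
everything normal (the encoder has already absorbed the anomalies). The
training set is therefore divided into *k* = 5 class-stratified,
patient-grouped folds; the encoder is fit on four folds and transforms
the fifth, so every feature vector comes from an encoder that never saw
its patient.

**The default encoder is quality-oriented.** `make_encoder("quality")`
emits coarse 8×8 pixels plus eight image-quality statistics — mean/sd
intensity, gradient-magnitude mean/sd, high-frequency (speckle-band)
energy, dark- and bright-pixel fractions, block contrast — standardized
column-wise with fold-fit means and scales. This choice is deliberate:
the corruptions worth removing are *quality* anomalies, and density-based
detectors only see them if the representation makes them extreme.
Raw-pixel or PCA-pixel features fail here in an instructive way: heavy
blurring moves an image *toward* the class mean (it strips the speckle
that all genuine frames carry), so in pixel space a blurred frame is an
inlier. In the quality statistics it is an extreme point on several axes
at once. A learned classifier embedding (`"tiny_mlp"`) and plain
`"pixel"`/`"pca"` encoders are available for comparison.

**Detectors.** Isolation Forest and Local Outlier Factor are implemented
in the package (axis-split forest with the standard `2^(-E[h]/c(ψ))`
score; classic k-NN LOF with index tie-breaks and an epsilon floor for
zero distances); the One-Class SVM wraps `e1071::svm`. All three are
reduced to one contract: score every row, flag exactly
`round(contamination × N)` top-scoring rows. Rank-thresholding keeps the
flagged fraction exact and makes determinism trivial. For the SVM, ν is
*not* tied to the contamination: a small ν forces the boundary to enclose
nearly all points, so gross outliers end up interior and invisible. The
default ν = 0.5 with γ = 0.35/d keeps the boundary soft; the rank
threshold then selects the flag count. Degenerate inputs (all rows
identical) produce tied scores and a documented index-order tie-break,
never a crash.

**Merge rule.** The per-detector *inlier* sets are merged by union: an
image is removed only when every detector flags it. This is the conservative way to combine independently selected
inlier sets: it caps the removed fraction at the smallest per-detector fraction, and it is exposed as
`rule = c("union", "majority", "intersection")`. With three detectors at
contamination 0.08, unanimity removes about 1–2% of clean images while
recovering planted blank/blur/occlude corruptions almost completely on
the synthetic cohort.

**What cleaning cannot do.** A label-swapped image (the appearance of
class B under the label of class A) is *not* a density outlier: its
features sit inside class B's distribution, which is itself dense. No
unsupervised detector on unlabeled feature vectors can flag it without
strong class separation. This is a structural limit, not a tuning
problem, and it motivates the soft-label stage.

## Stage 2 — cluster-distance soft labels

After cleaning, a class-aware encoder (`tiny_mlp`, 80 epochs by default)
is trained **on the cleaned set itself** and its hidden activations are
the soft-label features (`self_feature_extraction()`). Self-training
rather than out-of-fold is deliberate here and is the opposite of the
cleaning stage's requirement: the quantity of interest is the cluster
geometry the converged model forms over its own training images — images
it finds hard sit between clusters, and that is exactly the signal the
soft label should carry. At these encoder budgets the inverse-distance
weight's argmax agrees with the hard label for ≈97% of training images,
so the weights are informative rather than noise.

The pipeline stage order is: divide → clean → extract → soften.

**Reduction and clustering.** Features are reduced by the top `reduce_dim`
(default 8) principal directions, fit on cleaned training features only,
with a deterministic sign convention (the largest-magnitude loading of
each component is positive) so targets are exactly reproducible. A
stochastic neighbor embedding was rejected for this reason — targets must
be bit-reproducible. "Clustering" is class-conditional: one centroid per
class, the mean of that class's reduced vectors. An optional per-class
k-means refinement exists in the design space but is not implemented;
one centroid per category is the natural reading when each diagnosis is
treated as a single cluster.

**The softening formula.** With distances `d_c` to the centroids,

```
w_c      = (1 / max(d_c, eps)) / sum_j (1 / max(d_j, eps))
target_c = (onehot_c + tau * w_c) / (1 + tau)
```

The 1/(1+τ) normalization is the package's own choice: the raw sum of a
hard label and a τ-scaled inverse-distance ratio is not a distribution,
and cross-entropy training needs one. Dividing by (1+τ) is the minimal
normalization that preserves three provable properties, all
regression-tested: exact one-hot recovery at τ = 0, row-stochasticity for
every τ ≥ 0, and argmax preservation for τ ≤ 1 (the hard label
contributes 1/(1+τ), which exceeds any τ·w_c/(1+τ) since w_c ≤ 1).
ε defaults to 10⁻⁶ times the median inter-centroid distance, guarding the
zero-distance limit while leaving all realistic distances untouched.

τ is the smoothness knob: 0 is hard labels, the grid of practical
interest is 0.6–0.9 (`run_tau_sweep()`), and the package default is 0.7.
Learning τ, or per-sample adaptive τ, is out of scope.

## Stage 3 — soft-target training and patient-level ensembling

Two compact reference architectures are implemented natively so the whole
workflow runs on one CPU in minutes: `tiny_mlp` (256→32→K, ~8k
parameters) and `tiny_cnn` (one 3×3 convolution with 8 filters via
im2col, 2×2 mean-pooling, dense head; backward pass verified against
central-difference gradients). Both output log-softmax rows and train
with AdamW (decoupled weight decay on weights only) on the mean
soft-target cross-entropy `-Σ target·log p`, which reduces to standard
cross-entropy for one-hot targets — the τ = 0 trajectory-equality test
asserts this bitwise. Heavyweight backbone names (`resnet50`,
`densenet169/201`, `vgg16_bn`, `efficientnet_b4`, `vit_b`) are accepted
as registry slots for user-supplied implementations
(`register_architecture()`); nothing downloads weights.

Optimizer defaults: lr 5·10⁻³, weight decay 10⁻², batch 32, 80 epochs.
These were chosen so the compact networks actually reach the converged,
mildly overfit regime in which large pretrained backbones operate; at
lr 10⁻³ they stall far from convergence and every downstream comparison
measures optimization noise instead of data treatment.

Ensembling averages member *probabilities* (post-exponentiation) as a
weighted convex mixture — uniform weights by default, since nothing in
the method prescribes tuned weights — then averages a patient's image
rows and takes the argmax, ties broken to the lowest class index.
Patient aggregation and ensembling commute (both are linear), which is
asserted numerically. Macro-AUC is the unweighted mean of one-vs-rest
pairwise-rank AUCs with 0.5 credit for ties; ROC step-curve vertices are
returned such that their trapezoidal area equals the rank AUC exactly.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a two-view
ultrasound cohort, not its physics:

* a bright soft-edged ellipse (endometrium proxy) over a dark fan-shaped
  scan sector; the transverse view rotates the ellipse 90°;
* class appearance = a shared base point plus `separation` times a fixed
  per-class direction in (axis-ratio, texture-frequency, intensity,
  edge-softness) space, so `separation = 0` makes classes identically
  distributed and `class_separability()` grows monotonically with it;
* Rayleigh-like multiplicative speckle built from the squared sum of two
  smoothed Gaussian fields, normalized to unit mean;
* 2–4 images per patient (≈2.5 on average, matching a typical two-view
  acquisition), both views present whenever a patient has ≥2 images;
* planted outliers: `blank` (constant background), `blur` (heavy
  Gaussian), `occlude` (dark rectangle ≥25% of area), `label_swap`
  (rendered from another class's parameters, labeled with the patient's
  class); exactly `round(outlier_fraction × N)` images are corrupted and
  recorded in the ground truth.

Determinism is a first-class contract: each patient owns an RNG stream
keyed by (seed, patient index), so enlarging a cohort never perturbs
existing patients, and identical config + seed reproduces byte-identical
PNGs and manifest.

**What it does not emulate:** beamforming, attenuation, shadowing, probe
pressure, operator framing variability, scanner-specific post-processing,
or genuinely ambiguous histology. Passing tests on this generator
demonstrate that the machinery is correct and that the interventions act
in the documented directions under controlled noise — not that any
particular accuracy transfers to clinical data.

## The frozen evaluation conditions

The default pipeline configuration — the condition under which the
package's end-to-end behavior is tested — is: 20 patients per class,
separation 0.6 (substantially overlapping classes; single-model test
accuracy ≈0.7), 10% planted outliers across all four modes, contamination
0.08, τ = 0.7, members `tiny_mlp` + `tiny_cnn`, 80 epochs. Problem sizes
were chosen so a full three-arm ablation runs in ≈25 s per cohort
replicate on one CPU. Arms share member training seeds (a paired design),
so arm contrasts reflect the data treatment rather than fresh training
noise.

Under these conditions, measured over dozens of seeded replicates during
development:

* **Cleaning** raises mean patient-level ensemble accuracy by ≈3–5
  points whenever corruption is present — the robust effect.
* **Softening at τ = 0.7** is a small effect whose sign depends on the
  architecture and the residual noise in the cleaned set: single compact
  CNNs on a well-cleaned set gain ≈1–2 points, while ensembles — which
  already supply much of the same calibration benefit — show differences
  within ±1 point of zero. At this desk scale, cleaning and softening
  behave as partially *substitutable* regularizers; their gains do not
  stack the way they do for large overparameterized backbones on
  clinical-scale data, where the softening step has headroom that tiny
  well-regularized models lack.
* The uniform two-member ensemble virtually never falls below its worse
  member at the patient level (it failed on 0 of 32 decision-run seeds
  for the mixed-architecture pair).

These observations are reported here because the test suite asserts the
directional ordering base ≤ cleaned ≤ softened on means over its seed
set; a reader extending the package should know that the final link of
that chain is a small-margin effect at this scale, not a large one.

## Numerical and degenerate-input choices

* Distances: Euclidean throughout; squared-distance matrices computed by
  the expansion `‖x‖² − 2x·μ + ‖μ‖²` and clipped at zero before the
  square root.
* All stage seeds derive from one master seed through a fixed
  linear-congruential map (`stage_seed()`), staying below 2³¹; any stage
  can be rerun in isolation.
* Identical-feature inputs: detectors return tied scores; the rank
  threshold then flags the first `round(c·N)` indices — documented,
  deterministic, and exercised by tests.
* Empty class after cleaning, lo > hi image ranges, τ < 0, conflicting
  patient labels, duplicate image ids: all rejected with early,
  field-named errors; config validation reports *all* violations at once.
* `config_hash()` (MD5 of the canonical JSON serialization) stamps every
  run directory, making sweeps and ablations content-addressed.

## Known limitations

* The compact networks are stand-ins for the backbone contract, not
  competitive image classifiers; absolute accuracies on the synthetic
  cohort mean nothing clinically.
* Label-swap-type noise survives cleaning by construction (see Stage 1);
  at clinical scale with pathology-confirmed labels this mode should be
  rare.
* One centroid per class assumes unimodal class clusters in the reduced
  space; multi-morphology classes would need the per-class k-means
  refinement left out of scope here.
* The manifest is trusted: images are assumed already cropped to the
  scan region (an optional center-crop runs before resizing); DICOM
  ingestion and de-identification are out of scope.
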