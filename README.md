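# sonoclean

Training-set cleaning and soft-label enhancement for multiclass lesion
classification from 2-D ultrasound images.

## The problem

Classifiers for transvaginal-ultrasound images of endometrial lesions
(carcinoma vs. hyperplasia vs. polyp) are trained on retrospective,
multicenter image collections. Two properties of such data limit accuracy:

1. **Noisy training images.** Frames that are blanked, blurred, occluded by
   probe artifacts, or that capture the wrong structure slip through manual
   screening and degrade training.
2. **Overlapping class appearance.** Lesion types share sonographic
   features, so the one-hot label is an overconfident description of many
   images.

`sonoclean` implements a data-enhancement workflow that addresses both,
with the **patient (case) as the unit of every split and every metric**:

- **Out-of-fold feature extraction.** The training patients are divided
  into *k* class-stratified, patient-grouped folds; an encoder fit on
  *k*−1 folds produces the feature vector of each held-out image, so no
  image is scored by an encoder that saw its own patient.
- **Consensus cleaning.** Three anomaly detectors — Isolation Forest,
  Local Outlier Factor, and a One-Class SVM — score the feature vectors.
  Each flags its top `contamination` fraction; the per-detector inlier
  sets are merged by union, i.e. an image is removed only if **all**
  detectors flag it (unanimity).
- **Cluster-distance soft labels.** On the cleaned set, features are
  reduced to *d′* principal directions and each class *c* gets a centroid
  μ_c. For an image with distances d_c to the centroids, the weights and
  targets are

      w_c = (1 / max(d_c, ε)) / Σ_j (1 / max(d_j, ε))
      target_c = (onehot_c + τ · w_c) / (1 + τ)

  where τ ≥ 0 is an adjustable temperature (τ = 0 recovers one-hot; for
  τ ≤ 1 the argmax stays on the hard label). Rows sum to 1 by the 1/(1+τ)
  normalization, so the targets feed directly into soft-target
  cross-entropy.
- **Training and ensembling.** Members train with AdamW on the softened
  targets (log-softmax outputs, soft cross-entropy loss). At test time,
  member probability rows are combined as a weighted convex mixture, all
  image rows of one patient are averaged, and the patient's class is the
  argmax. Reported metrics: accuracy, one-vs-rest macro-AUC (pairwise rank
  with 0.5 tie credit), per-class recall/precision/F1/specificity,
  confusion matrix, ROC points.

A deterministic **synthetic cohort generator** (bright ellipse on a dark
fan-shaped sector, Rayleigh-like multiplicative speckle, two acquisition
views, planted blank/blur/occlude/label-swap outliers) makes the full
workflow testable without clinical data.

## Worked example

```r
library(sonoclean)

cohort <- generate_cohort(
  synthetic_config(n_patients_per_class = 20, separation = 0.6,
                   outlier_fraction = 0.10, seed = 42),
  tempfile("cohort"))
cohort$manifest
#> cohort_manifest: 173 images, 60 patients, 3 classes
#> cancer  hyper  polyp
#>     20     20     20

split <- stratified_patient_split(cohort$manifest, test_fraction = 0.3, seed = 42)
train <- split_manifest(cohort$manifest, split, "train")
test  <- split_manifest(cohort$manifest, split, "test")

feats   <- kfold_feature_extraction(train, make_encoder("quality"), k = 5, seed = 42)
cleaned <- clean_training_set(train, feats, default_detector_configs(0.08, seed = 42))
cleaned$report
#> cleaning_report (union): 7 removed, 112 retained
```

Six of the seven removals are planted corruptions (the label-swapped
images are *not* density outliers in feature space and survive — see the
vignette for why softening, not cleaning, is the tool for those).

```r
soft_feats <- self_feature_extraction(cleaned$manifest,
                                      make_encoder("tiny_mlp", epochs = 80, seed = 42))
softened <- build_softened_set(cleaned$manifest, soft_feats, soft_label_config(tau = 0.7))
round(softened$soft_labels$targets[1:3, ], 3)
#>              cancer hyper polyp
#> pt0004_img01  0.808 0.083 0.109
#> pt0004_img02  0.843 0.071 0.086
#> pt0004_img03  0.884 0.057 0.059
```

Each row is a probability target: most mass on the diagnosis, the
remainder spread by inverse cluster distance.

```r
members <- list(
  train_classifier(cleaned$manifest, softened$soft_labels,
    model_spec("tiny_mlp", n_classes = 3), train_config(seed = 1), tag = "mlp"),
  train_classifier(cleaned$manifest, softened$soft_labels,
    model_spec("tiny_cnn", n_classes = 3), train_config(seed = 2), tag = "cnn"))
tables   <- lapply(members, predict_image_probabilities, manifest = test)
ensemble <- ensemble_probabilities(tables)
compute_metrics(aggregate_patient(ensemble), patient_classes(cohort$manifest))
#> metrics_report: 18 patients | accuracy 0.7778 | macro-AUC 0.9398
#>         predicted
#> truth    cancer hyper polyp
#>   cancer      6     0     0
#>   hyper       0     4     2
#>   polyp       1     1     4
```

18 test patients (6 per class), 14 classified correctly; carcinoma is
fully recovered and the errors sit on the hyperplasia/polyp boundary,
the visually closest pair.

`run_pipeline(config, out_dir)` drives the same stages from one YAML
config with stage-derived seeds, a config hash on every artifact, and an
image-access audit; `run_ablation()` compares base / cleaned / softened
arms on a shared cohort, and `run_tau_sweep()` scans the temperature grid.
A thin CLI over these functions ships in `inst/scripts/sonoclean`.

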