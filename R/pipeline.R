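# Pipeline orchestration: one YAML config drives simulate -> split ->
# out-of-fold features -> clean -> soften -> train -> predict -> ensemble ->
# evaluate, with stage-derived seeds, a config hash on every artifact, and
# an image-access audit that proves the test split is untouched before
# prediction.

# Stage-name -> stream index for seed derivation. A single master seed fans
# out through derive_seed(master, index) so any stage can be rerun alone.
.stage_streams <- c(
  simulate = 11L, split = 22L, features = 33L, clean = 44L,
  soften = 55L, train = 66L, predict = 77L, evaluate = 88L
)

#' Derive a stage seed from the master seed
#'
#' @param master integer master seed.
#' @param stage one of `names(sonoclean:::.stage_streams)`.
#' @param offset extra offset (e.g. member index, repeat index).
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(master, stage, offset = 0L) {
  if (!stage %in% names(.stage_streams)) {
    stop("unknown stage: ", stage)
  }
  derive_seed(master, .stage_streams[[stage]] + 1000L * offset)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(
      simulate = list(
        classes = c("cancer", "hyper", "polyp"),
        n_patients_per_class = 20L,
        images_per_patient = c(2L, 4L),
        image_size = 64L,
        separation = 0.6,
        speckle_sigma = 0.4,
        outlier_fraction = 0.10,
        outlier_modes = c("blank", "blur", "occlude", "label_swap")
      ),
      manifest = NULL
    ),
    split = list(test_fraction = 0.3),
    cleaning = list(
      k = 5L, encoder = "quality", encoder_size = 16L, encoder_dim = 16L,
      contamination = 0.08,
      detectors = c("isolation_forest", "local_outlier_factor", "one_class_svm"),
      merge_rule = "union"
    ),
    soften = list(
      tau = 0.7, reduce_dim = 8L, reducer = "linear_projection",
      encoder = "tiny_mlp", encoder_size = 16L, encoder_dim = 16L,
      encoder_epochs = 80L
    ),
    train = list(
      epochs = 80L, batch_size = 32L, lr = 5e-3, weight_decay = 1e-2,
      augment = FALSE, input_size = 16L, hidden = 32L,
      members = list(
        list(architecture = "tiny_mlp", tag = "tiny_mlp_a"),
        list(architecture = "tiny_cnn", tag = "tiny_cnn_b")
      )
    ),
    ensemble = list(weights = NULL)
  )
}

# Deep-merge user values over defaults (lists merged by name).
merge_config <- function(default, user) {
  if (is.null(user)) {
    return(default)
  }
  if (!is.list(default) || !is.list(user) || is.null(names(default))) {
    return(user)
  }
  for (nm in names(user)) {
    merged <- if (nm %in% names(default)) {
      merge_config(default[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
    default[nm] <- list(merged) # keeps NULL-valued fields present
  }
  default
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML file, fills missing fields with package defaults (warning
#' once per injected top-level section), and checks every constraint,
#' collecting all violations rather than stopping at the first.
#'
#' @param path YAML file path, or a list already in memory.
#' @return an object of class `pipeline_config`; if any constraint fails,
#'   an error listing every violation.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else {
    path
  }
  defaults <- default_pipeline_config()
  injected <- setdiff(names(defaults), names(user))
  if (length(injected) > 0L && length(user) > 0L) {
    warning("config sections defaulted: ", paste(injected, collapse = ", "))
  }
  cfg <- merge_config(defaults, user)

  errors <- character(0)
  check <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)

  check(is.numeric(cfg$seed) && cfg$seed == floor(cfg$seed), "seed: must be an integer")
  sf <- cfg$split$test_fraction
  check(is.numeric(sf) && sf > 0 && sf < 1, "split.test_fraction: must be in (0, 1)")
  check(cfg$cleaning$k >= 2, "cleaning.k: must be >= 2")
  check(
    cfg$cleaning$contamination >= 0 && cfg$cleaning$contamination < 0.5,
    "cleaning.contamination: must be in [0, 0.5)"
  )
  check(
    all(cfg$cleaning$detectors %in%
      c("isolation_forest", "local_outlier_factor", "one_class_svm")),
    "cleaning.detectors: unknown detector name"
  )
  check(
    cfg$cleaning$merge_rule %in% c("union", "majority", "intersection"),
    "cleaning.merge_rule: must be union, majority or intersection"
  )
  check(is.numeric(cfg$soften$tau) && cfg$soften$tau >= 0, "soften.tau: must be >= 0")
  check(cfg$soften$reduce_dim >= 2, "soften.reduce_dim: must be >= 2")
  check(cfg$train$epochs >= 1, "train.epochs: must be >= 1")
  check(cfg$train$lr > 0, "train.lr: must be positive")
  check(length(cfg$train$members) >= 1, "train.members: need at least one member")
  if (!is.null(cfg$cohort$simulate)) {
    sim <- cfg$cohort$simulate
    check(
      sim$outlier_fraction >= 0 && sim$outlier_fraction < 1,
      "cohort.simulate.outlier_fraction: must be in [0, 1)"
    )
    check(sim$separation >= 0, "cohort.simulate.separation: must be >= 0")
  }
  if (length(errors) > 0L) {
    stop("invalid pipeline config:\n  ", paste(errors, collapse = "\n  "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' MD5 over the canonical JSON serialization; stamped into every artifact
#' directory so reruns and cached sweeps are content-addressed.
#'
#' @param config a `pipeline_config` (or any list).
#' @return a 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(
    as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)),
    tmp
  )
  unname(tools::md5sum(tmp))
}

# Soft-label stage: train a class-aware encoder on the cleaned training set
# itself, extract its features, and build the temperature-softened targets.
# Self-training (not out-of-fold) is deliberate here: the cluster geometry
# the converged model forms over its own training images is what the
# inverse-distance weights are meant to measure.
soften_stage <- function(cfg, cleaned_man) {
  enc <- make_encoder(cfg$soften$encoder,
    size = cfg$soften$encoder_size, dim = cfg$soften$encoder_dim,
    epochs = cfg$soften$encoder_epochs,
    seed = stage_seed(cfg$seed, "soften")
  )
  feats <- self_feature_extraction(cleaned_man, enc)
  build_softened_set(
    cleaned_man, feats,
    soft_label_config(
      tau = cfg$soften$tau,
      reduce_dim = cfg$soften$reduce_dim, reducer = cfg$soften$reducer
    )
  )
}

member_specs <- function(cfg, classes) {
  lapply(seq_along(cfg$train$members), function(m) {
    mem <- cfg$train$members[[m]]
    list(
      spec = model_spec(
        architecture = mem$architecture %||% "tiny_mlp",
        n_classes = length(classes),
        input_size = mem$input_size %||% cfg$train$input_size,
        hidden = mem$hidden %||% cfg$train$hidden
      ),
      tag = mem$tag %||% paste0(mem$architecture %||% "tiny_mlp", "_", m),
      offset = m
    )
  })
}

train_members <- function(cfg, manifest, targets, master_seed, arm_offset = 0L) {
  specs <- member_specs(cfg, manifest$classes)
  lapply(specs, function(mem) {
    tc <- train_config(
      epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
      lr = cfg$train$lr, weight_decay = cfg$train$weight_decay,
      augment = cfg$train$augment,
      seed = stage_seed(master_seed, "train", mem$offset + 100L * arm_offset)
    )
    train_classifier(manifest, targets, mem$spec, tc, tag = mem$tag)
  })
}

predict_and_score <- function(models, cfg, test_manifest, truth) {
  tables <- lapply(models, predict_image_probabilities, manifest = test_manifest)
  ens <- if (length(tables) > 1L) {
    ensemble_probabilities(
      tables,
      ensemble_spec(
        vapply(models, function(m) m$tag, character(1)),
        cfg$ensemble$weights
      )
    )
  } else {
    tables[[1]]
  }
  patients <- aggregate_patient(ens)
  list(
    member_tables = tables,
    ensemble_table = ens,
    patient_table = patients,
    metrics = compute_metrics(patients, truth)
  )
}

#' Run the full enhancement pipeline
#'
#' Executes every stage under one config and writes all artifacts into
#' `out_dir`: manifest (when simulated), split JSON, out-of-fold features,
#' cleaning report, soft labels, per-member training histories, member and
#' ensemble prediction CSVs, and `metrics.json`. Every run directory gets a
#' `config.json` plus its hash. The image-access audit runs throughout;
#' test-split images are read only in the predict stage.
#'
#' @param config a `pipeline_config` (see [validate_config()]) or a path to
#'   a YAML file.
#' @param out_dir run directory (created).
#' @param arm `"softened"` (full pipeline, default), `"cleaned"` (cleaning
#'   but hard labels) or `"base"` (no cleaning, hard labels).
#' @return list with `metrics` (a `metrics_report`), `report`
#'   (`cleaning_report` or NULL), `paths`, `audit` (the access log).
#' @export
run_pipeline <- function(config, out_dir, arm = c("softened", "cleaned", "base")) {
  arm <- match.arg(arm)
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  jsonlite::write_json(
    c(unclass(cfg), list(config_hash = hash, arm = arm)),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  audit_images(TRUE)
  on.exit(audit_images(FALSE))

  # cohort
  set_audit_stage("simulate")
  if (!is.null(cfg$cohort$manifest)) {
    manifest <- load_manifest(cfg$cohort$manifest)
  } else {
    sim <- cfg$cohort$simulate
    sc <- synthetic_config(
      classes = sim$classes,
      n_patients_per_class = sim$n_patients_per_class,
      images_per_patient = unlist(sim$images_per_patient),
      image_size = sim$image_size,
      separation = sim$separation,
      speckle_sigma = sim$speckle_sigma,
      outlier_fraction = sim$outlier_fraction,
      outlier_modes = sim$outlier_modes,
      seed = stage_seed(cfg$seed, "simulate")
    )
    manifest <- generate_cohort(sc, file.path(out_dir, "cohort"))$manifest
  }

  # split
  set_audit_stage("split")
  split <- stratified_patient_split(
    manifest, cfg$split$test_fraction,
    seed = stage_seed(cfg$seed, "split")
  )
  write_split(split, file.path(out_dir, "split.json"))
  train_man <- split_manifest(manifest, split, "train")
  test_man <- split_manifest(manifest, split, "test")

  # out-of-fold features + cleaning
  report <- NULL
  cleaned_man <- train_man
  feats <- NULL
  if (arm %in% c("cleaned", "softened")) {
    set_audit_stage("features")
    enc <- make_encoder(cfg$cleaning$encoder,
      size = cfg$cleaning$encoder_size, dim = cfg$cleaning$encoder_dim,
      seed = stage_seed(cfg$seed, "features")
    )
    feats <- kfold_feature_extraction(train_man, enc,
      k = cfg$cleaning$k,
      seed = stage_seed(cfg$seed, "features")
    )
    utils::write.csv(
      data.frame(image_id = feats$image_ids, fold = feats$fold_of, feats$x),
      file.path(out_dir, "features.csv"),
      row.names = FALSE
    )
    set_audit_stage("clean")
    configs <- lapply(
      cfg$cleaning$detectors,
      function(m) {
        detector_config(m, cfg$cleaning$contamination,
          seed = stage_seed(cfg$seed, "clean")
        )
      }
    )
    cleaned <- clean_training_set(train_man, feats, configs, rule = cfg$cleaning$merge_rule)
    cleaned_man <- cleaned$manifest
    report <- cleaned$report
    write_cleaning_report(report, file.path(out_dir, "cleaning_report.json"))
  }

  # soft labels; features re-extracted from the cleaned set
  # (stage order: divide -> clean -> extract -> soften)
  targets <- NULL
  if (arm == "softened") {
    set_audit_stage("soften")
    softened <- soften_stage(cfg, cleaned_man)
    targets <- softened$soft_labels
    write_soft_labels(targets, file.path(out_dir, "soft_labels.csv"))
  }

  # train members
  set_audit_stage("train")
  models <- train_members(cfg, cleaned_man, targets, cfg$seed)
  for (m in models) {
    utils::write.csv(
      data.frame(epoch = seq_along(m$fit$history), loss = m$fit$history),
      file.path(out_dir, paste0("history_", m$tag, ".csv")),
      row.names = FALSE
    )
  }

  # predict + evaluate (the only stages allowed to read test images)
  set_audit_stage("predict")
  scored <- predict_and_score(models, cfg, test_man, patient_classes(manifest))
  set_audit_stage("evaluate")
  for (tab in scored$member_tables) {
    write_predictions(tab, file.path(out_dir, paste0("pred_", tab$model_tag[1], ".csv")))
  }
  write_predictions(scored$ensemble_table, file.path(out_dir, "pred_ensemble.csv"))
  write_metrics(scored$metrics, file.path(out_dir, "metrics.json"))

  list(
    metrics = scored$metrics, report = report, split = split,
    config_hash = hash,
    paths = list(out_dir = out_dir),
    audit = audit_log()
  )
}

#' Base / cleaned / softened ablation
#'
#' Runs the three processing arms on one shared cohort and split: `base`
#' trains on the uncleaned training set with hard labels, `cleaned` on the
#' consensus-cleaned set with hard labels, `softened` on the cleaned set
#' with temperature-softened targets. Features, cleaning and soft labels
#' are computed once and shared, so the arms differ only in their training
#' targets and manifests.
#'
#' @param config a `pipeline_config` or YAML path.
#' @param out_dir optional directory for cohort artifacts (a tempdir by
#'   default).
#' @return data.frame with one row per arm: `arm`, `accuracy`, `macro_auc`,
#'   plus member accuracies as attributes `member_accuracy`.
#' @export
run_ablation <- function(config, out_dir = tempfile("ablation")) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- cfg$cohort$simulate
  if (!is.null(cfg$cohort$manifest)) {
    manifest <- load_manifest(cfg$cohort$manifest)
  } else {
    sc <- synthetic_config(
      classes = sim$classes,
      n_patients_per_class = sim$n_patients_per_class,
      images_per_patient = unlist(sim$images_per_patient),
      image_size = sim$image_size,
      separation = sim$separation,
      speckle_sigma = sim$speckle_sigma,
      outlier_fraction = sim$outlier_fraction,
      outlier_modes = sim$outlier_modes,
      seed = stage_seed(cfg$seed, "simulate")
    )
    manifest <- generate_cohort(sc, file.path(out_dir, "cohort"))$manifest
  }
  split <- stratified_patient_split(manifest, cfg$split$test_fraction,
    seed = stage_seed(cfg$seed, "split")
  )
  train_man <- split_manifest(manifest, split, "train")
  test_man <- split_manifest(manifest, split, "test")
  truth <- patient_classes(manifest)

  enc <- make_encoder(cfg$cleaning$encoder,
    size = cfg$cleaning$encoder_size, dim = cfg$cleaning$encoder_dim,
    seed = stage_seed(cfg$seed, "features")
  )
  feats <- kfold_feature_extraction(train_man, enc,
    k = cfg$cleaning$k,
    seed = stage_seed(cfg$seed, "features")
  )
  configs <- lapply(cfg$cleaning$detectors, function(m) {
    detector_config(m, cfg$cleaning$contamination, seed = stage_seed(cfg$seed, "clean"))
  })
  cleaned <- clean_training_set(train_man, feats, configs, rule = cfg$cleaning$merge_rule)
  softened <- soften_stage(cfg, cleaned$manifest)

  # paired design: all arms share the member training seeds, so arm
  # contrasts are driven by the data treatment, not by fresh training noise
  arms <- list(
    base = list(manifest = train_man, targets = NULL),
    cleaned = list(manifest = cleaned$manifest, targets = NULL),
    softened = list(manifest = cleaned$manifest, targets = softened$soft_labels)
  )
  rows <- list()
  member_acc <- list()
  for (arm in names(arms)) {
    a <- arms[[arm]]
    models <- train_members(cfg, a$manifest, a$targets, cfg$seed)
    scored <- predict_and_score(models, cfg, test_man, truth)
    rows[[arm]] <- data.frame(
      arm = arm,
      accuracy = scored$metrics$accuracy,
      macro_auc = scored$metrics$macro_auc,
      stringsAsFactors = FALSE
    )
    member_acc[[arm]] <- vapply(scored$member_tables, function(tab) {
      compute_metrics(aggregate_patient(tab), truth)$accuracy
    }, numeric(1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "member_accuracy") <- member_acc
  attr(out, "cleaning_report") <- cleaned$report
  out
}

#' Temperature sweep
#'
#' Runs the softened arm at each temperature on one shared cohort, split,
#' cleaning and feature extraction; only the soft targets and training
#' differ.
#'
#' @param config a `pipeline_config` or YAML path.
#' @param taus temperature grid (default the reference grid 0.6--0.9).
#' @param out_dir optional artifact directory.
#' @return data.frame with one row per tau: `tau`, `accuracy`, `macro_auc`.
#' @export
run_tau_sweep <- function(config, taus = c(0.6, 0.7, 0.8, 0.9),
                          out_dir = tempfile("tausweep")) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  rows <- lapply(seq_along(taus), function(i) {
    cfg_i <- cfg
    cfg_i$soften$tau <- taus[i]
    ab <- run_ablation(cfg_i, out_dir = file.path(out_dir, paste0("tau", i)))
    data.frame(
      tau = taus[i],
      accuracy = ab$accuracy[ab$arm == "softened"],
      macro_auc = ab$macro_auc[ab$arm == "softened"]
    )
  })
  do.call(rbind, rows)
}
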