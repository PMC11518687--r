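# Out-of-fold feature extraction over patient-grouped, class-stratified
# folds, and consensus cleaning of the training set.

#' Construct a feature encoder
#'
#' An encoder is a pair of functions with signature
#' `fit(images, labels) -> state` and `transform(state, images) -> matrix`
#' where `images` is a list of `[0, 1]` matrices. The encoder is (re)fit on
#' each fold's training images only, so transformed held-out images never
#' see their own patient during fitting.
#'
#' Built-in encoders:
#' \describe{
#'   \item{quality}{(default) coarse 8 x 8 pixels plus image-quality
#'     statistics (mean/sd intensity, gradient-magnitude mean/sd,
#'     high-frequency speckle energy, dark and bright pixel fractions,
#'     block contrast), standardized column-wise with means/sds fit on the
#'     fold-training images. Quality corruptions -- blanked, blurred or
#'     occluded frames -- are extreme in several of these coordinates at
#'     once, which is what the downstream anomaly detectors need.}
#'   \item{pixel}{no fitting; downsample to `size` x `size` and flatten.}
#'   \item{pca}{downsample, flatten, then project onto the top `dim`
#'     principal directions fit on the fold-training images (deterministic
#'     sign convention: largest-magnitude loading positive).}
#'   \item{tiny_mlp}{train a small soft-max classifier on the fold-training
#'     images (hard labels) and emit its hidden-layer activations.}
#' }
#'
#' @param name encoder name.
#' @param size downsampling side length before flattening.
#' @param dim output dimension (pca and tiny_mlp).
#' @param epochs,seed tiny_mlp training budget and seed.
#' @return an object of class `feature_encoder`.
#' @export
make_encoder <- function(name = c("quality", "pca", "pixel", "tiny_mlp"),
                         size = 16L, dim = 16L, epochs = 20L, seed = 1L) {
  name <- match.arg(name)
  flatten <- function(images) {
    t(vapply(images, function(m) as.numeric(resize_matrix(m, size)), numeric(size^2)))
  }
  enc <- switch(name,
    quality = list(
      fit = function(images, labels) {
        x <- t(vapply(images, quality_features, numeric(72L)))
        list(mu = colMeans(x), sd = pmax(apply(x, 2L, stats::sd), 1e-8))
      },
      transform = function(state, images) {
        x <- t(vapply(images, quality_features, numeric(72L)))
        scale(x, center = state$mu, scale = state$sd)[, , drop = FALSE]
      }
    ),
    pixel = list(
      fit = function(images, labels) list(),
      transform = function(state, images) flatten(images)
    ),
    pca = list(
      fit = function(images, labels) {
        x <- flatten(images)
        d <- min(dim, nrow(x) - 1L, ncol(x))
        pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
        rot <- pr$rotation
        # sign convention: largest-|loading| entry of each PC is positive
        for (j in seq_len(ncol(rot))) {
          peak <- which.max(abs(rot[, j]))
          if (rot[peak, j] < 0) rot[, j] <- -rot[, j]
        }
        list(center = pr$center, rotation = rot)
      },
      transform = function(state, images) {
        sweep(flatten(images), 2L, state$center) %*% state$rotation
      }
    ),
    tiny_mlp = list(
      fit = function(images, labels) {
        classes <- sort(unique(labels))
        spec <- model_spec("tiny_mlp",
          n_classes = length(classes),
          input_size = size, hidden = dim
        )
        targets <- one_hot(match(labels, classes), length(classes))
        fit <- train_network(flatten(images), targets, spec,
          train_config(epochs = epochs, seed = seed)
        )
        list(fit = fit, classes = classes)
      },
      transform = function(state, images) {
        network_hidden(state$fit, flatten(images))
      }
    )
  )
  structure(c(enc, list(name = name, size = size)), class = "feature_encoder")
}

# Coarse pixels + image-quality statistics for one [0,1] matrix: the raw
# representation behind the "quality" encoder. 8x8 pixels (64) followed by
# mean/sd intensity, gradient mean/sd, high-frequency (speckle) energy,
# dark fraction, bright fraction, block contrast (8) = 72 features.
quality_features <- function(img) {
  gx <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  gy <- img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  gm <- sqrt(gx[-nrow(gx), , drop = FALSE]^2 + gy[, -ncol(gy), drop = FALSE]^2)
  smooth <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(img), sigma = 1.5)
  ))
  hf <- (img - smooth)^2
  blocks <- resize_matrix(img, 4L)
  c(
    as.numeric(resize_matrix(img, 8L)),
    mean(img), stats::sd(img), mean(gm), stats::sd(gm), mean(hf),
    mean(img < 0.05), mean(img > 0.5), stats::sd(blocks)
  )
}

# Class-stratified, patient-grouped fold assignment: patient -> fold index.
assign_patient_folds <- function(manifest, k, seed) {
  pc <- patient_classes(manifest)
  fold_of <- integer(0)
  for (cl in manifest$classes) {
    pats <- sort(names(pc)[pc == cl])
    if (length(pats) < k) {
      stop("class ", cl, " has ", length(pats), " training patients; needs >= k = ", k)
    }
    pats <- with_local_seed(
      derive_seed(seed, 100L + match(cl, manifest$classes)),
      sample(pats)
    )
    fold_of <- c(fold_of, stats::setNames(
      rep_len(seq_len(k), length(pats)), pats
    ))
  }
  fold_of
}

#' Out-of-fold feature extraction
#'
#' Partitions the training patients into `k` folds (stratified by class,
#' grouped by patient) and, for each fold, fits the encoder on the other
#' folds' images and transforms the held-out fold's images. Every training
#' image thus receives a feature vector from an encoder that never saw its
#' patient, preventing self-memorization in the downstream anomaly scoring.
#'
#' @param train_manifest training-side `cohort_manifest`.
#' @param encoder a [make_encoder()] object.
#' @param k number of folds (>= 2); every class needs >= k patients.
#' @param seed integer seed for fold assignment (and encoder fitting where
#'   stochastic).
#' @return an object of class `feature_matrix`: list with `image_ids`,
#'   `x` (N x d matrix, rownames = image ids), `fold_of` (named integer),
#'   `encoder_tag`.
#' @export
kfold_feature_extraction <- function(train_manifest, encoder = make_encoder("quality"),
                                     k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  records <- train_manifest$records
  fold_of_patient <- assign_patient_folds(train_manifest, k, seed)
  fold_of_image <- fold_of_patient[records$patient_id]
  names(fold_of_image) <- records$image_id

  images <- lapply(records$path, read_image)
  names(images) <- records$image_id

  blocks <- list()
  for (f in seq_len(k)) {
    held <- records$image_id[fold_of_image == f]
    rest <- records$image_id[fold_of_image != f]
    state <- encoder$fit(images[rest], records$class[match(rest, records$image_id)])
    feats <- encoder$transform(state, images[held])
    rownames(feats) <- held
    blocks[[f]] <- feats
  }
  d <- min(vapply(blocks, ncol, integer(1)))
  x <- do.call(rbind, lapply(blocks, function(b) b[, seq_len(d), drop = FALSE]))
  x <- x[records$image_id, , drop = FALSE]
  structure(
    list(
      image_ids = records$image_id, x = x,
      fold_of = fold_of_image, encoder_tag = encoder$name
    ),
    class = "feature_matrix"
  )
}

#' Whole-set feature extraction
#'
#' Fits the encoder on all of a manifest's images and transforms the same
#' images. Unlike [kfold_feature_extraction()] this is *not* leakage-free
#' and must never feed anomaly scoring; it is intended for the soft-label
#' stage, where the cluster geometry of a representation trained on the
#' cleaned set itself is wanted (the class clusters a converged model forms
#' are what the inverse-distance weights measure).
#'
#' @param manifest a `cohort_manifest`.
#' @param encoder a [make_encoder()] object.
#' @return a `feature_matrix` (with `fold_of = NULL`).
#' @export
self_feature_extraction <- function(manifest, encoder = make_encoder("tiny_mlp")) {
  records <- manifest$records
  images <- lapply(records$path, read_image)
  state <- encoder$fit(images, records$class)
  x <- encoder$transform(state, images)
  rownames(x) <- records$image_id
  structure(
    list(
      image_ids = records$image_id, x = x,
      fold_of = NULL, encoder_tag = paste0(encoder$name, "_self")
    ),
    class = "feature_matrix"
  )
}

#' Merge per-detector outlier masks into a cleaning report
#'
#' Under the default `"union"` rule the per-detector inlier (selected) sets
#' are unioned, i.e. an image is removed only if every detector flags it;
#' `"majority"` removes images flagged by more than half the detectors and
#' `"intersection"` removes images flagged by any detector.
#'
#' @param flag_masks list of equal-length logical vectors (`TRUE` = outlier),
#'   ideally named by image id.
#' @param rule merge rule.
#' @param image_ids optional image ids (taken from mask names otherwise).
#' @return an object of class `cleaning_report`: list with `flags`
#'   (N x n_detector logical matrix), `removed_ids`, `retained_ids`,
#'   `merge_rule`.
#' @export
merge_inlier_sets <- function(flag_masks, rule = c("union", "majority", "intersection"),
                              image_ids = NULL) {
  rule <- match.arg(rule)
  if (length(flag_masks) < 1L) stop("need at least one mask")
  n <- length(flag_masks[[1]])
  if (!all(vapply(flag_masks, length, integer(1)) == n)) {
    stop("all masks must have equal length")
  }
  if (is.null(image_ids)) image_ids <- names(flag_masks[[1]])
  if (is.null(image_ids)) image_ids <- as.character(seq_len(n))
  flags <- do.call(cbind, flag_masks)
  rownames(flags) <- image_ids
  if (is.null(colnames(flags))) {
    colnames(flags) <- paste0("detector", seq_along(flag_masks))
  }
  n_flagged <- rowSums(flags)
  removed <- switch(rule,
    union = n_flagged == length(flag_masks), # unanimity to remove
    majority = n_flagged > length(flag_masks) / 2,
    intersection = n_flagged > 0L
  )
  structure(
    list(
      flags = flags,
      removed_ids = image_ids[removed],
      retained_ids = image_ids[!removed],
      merge_rule = rule
    ),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(
    "cleaning_report (", x$merge_rule, "): ",
    length(x$removed_ids), " removed, ",
    length(x$retained_ids), " retained\n",
    sep = ""
  )
  invisible(x)
}

#' Clean a training set by detector consensus
#'
#' Runs every configured detector on the out-of-fold features, merges the
#' masks with [merge_inlier_sets()], and drops the removed images from the
#' training manifest. The test split is never an input to this function.
#'
#' @param train_manifest training-side `cohort_manifest`.
#' @param features a `feature_matrix` covering exactly the manifest's images.
#' @param detector_configs list of [detector_config()] objects.
#' @param rule merge rule, see [merge_inlier_sets()].
#' @return list with `manifest` (cleaned `cohort_manifest`) and `report`
#'   (`cleaning_report`).
#' @export
clean_training_set <- function(train_manifest, features,
                               detector_configs = default_detector_configs(),
                               rule = "union") {
  records <- train_manifest$records
  if (!setequal(features$image_ids, records$image_id)) {
    stop("feature matrix does not cover the training manifest")
  }
  masks <- lapply(detector_configs, function(cfg) detect_outliers(features, cfg))
  names(masks) <- vapply(detector_configs, function(cfg) cfg$method, character(1))
  report <- merge_inlier_sets(masks, rule = rule, image_ids = features$image_ids)
  cleaned <- manifest_from_records(
    records[records$image_id %in% report$retained_ids, , drop = FALSE],
    train_manifest$classes
  )
  list(manifest = cleaned, report = report)
}

#' Default three-detector configuration
#'
#' Isolation Forest, Local Outlier Factor, and One-Class SVM at a common
#' contamination level.
#'
#' @param contamination shared contamination fraction.
#' @param seed integer seed.
#' @return list of three [detector_config()] objects.
#' @export
default_detector_configs <- function(contamination = 0.05, seed = 1L) {
  list(
    detector_config("isolation_forest", contamination, seed),
    detector_config("local_outlier_factor", contamination, seed),
    detector_config("one_class_svm", contamination, seed)
  )
}

#' Persist a cleaning report as JSON
#'
#' @param report a `cleaning_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(
    list(
      merge_rule = report$merge_rule,
      removed_ids = report$removed_ids,
      retained_ids = report$retained_ids,
      flags = as.data.frame(report$flags)
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
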