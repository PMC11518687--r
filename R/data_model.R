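# Cohort roster, patient-level stratified split, preprocessing contract.

#' Load and validate a cohort manifest
#'
#' Reads a CSV with columns `image_id, patient_id, class, path` (optional
#' `view`, `is_outlier`). Relative `path` entries are resolved against the
#' manifest's directory. Validation rejects duplicate image ids and patients
#' carrying more than one class label — every image of a patient must share
#' the patient's diagnosis, because all evaluation is per patient.
#'
#' @param path CSV file path.
#' @param classes optional ordered class vector; defaults to the sorted
#'   classes present.
#' @return an object of class `cohort_manifest`: list with `records`
#'   (data.frame) and `classes` (character).
#' @export
load_manifest <- function(path, classes = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "patient_id", "class", "path")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"view" %in% names(tab)) tab$view <- "unknown"
  rel <- !grepl("^(/|[A-Za-z]:)", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  manifest_from_records(tab, classes)
}

# Shared validator for manifests built from a data.frame.
manifest_from_records <- function(records, classes = NULL) {
  if (anyDuplicated(records$image_id) > 0L) {
    dup <- records$image_id[duplicated(records$image_id)][1]
    stop("duplicate image_id in manifest: ", dup)
  }
  lab_per_pat <- tapply(records$class, records$patient_id, function(x) length(unique(x)))
  if (any(lab_per_pat > 1L)) {
    bad <- names(lab_per_pat)[lab_per_pat > 1L][1]
    stop("patient ", bad, " carries conflicting class labels")
  }
  if (is.null(classes)) classes <- sort(unique(records$class))
  if (!all(records$class %in% classes)) {
    stop(
      "manifest contains classes outside the declared set: ",
      paste(setdiff(unique(records$class), classes), collapse = ", ")
    )
  }
  structure(
    list(records = records, classes = classes),
    class = "cohort_manifest"
  )
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(
    "cohort_manifest:", nrow(x$records), "images,",
    length(unique(x$records$patient_id)), "patients,",
    length(x$classes), "classes\n"
  )
  print(table(x$records$class[!duplicated(x$records$patient_id)]))
  invisible(x)
}

#' Patient-to-class lookup
#'
#' One class label per patient (a manifest invariant); the truth vector used
#' by [compute_metrics()].
#'
#' @param manifest a `cohort_manifest`.
#' @return named character vector, names = patient ids.
#' @export
patient_classes <- function(manifest) {
  r <- manifest$records
  keep <- !duplicated(r$patient_id)
  stats::setNames(r$class[keep], r$patient_id[keep])
}

#' Stratified patient-level train/test split
#'
#' The split unit is the patient (the case), never the image: all images of
#' one patient land on the same side. Within each class,
#' `round_half_away(test_fraction * n_patients)` patients are sampled without
#' replacement into the test set; e.g. class patient counts (168, 290, 276)
#' at 30% give test counts (50, 87, 83).
#'
#' @param manifest a `cohort_manifest`.
#' @param test_fraction fraction in (0, 1) of patients per class to hold out.
#' @param seed integer seed; identical seeds reproduce identical membership.
#' @return object of class `split_assignment`: list with
#'   `train_patient_ids`, `test_patient_ids`, `seed`, `test_fraction`.
#' @export
stratified_patient_split <- function(manifest, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  pc <- patient_classes(manifest)
  test_ids <- character(0)
  for (cl in manifest$classes) {
    pats <- sort(names(pc)[pc == cl])
    if (length(pats) == 0L) stop("class has no patients: ", cl)
    n_test <- round_half_away(test_fraction * length(pats))
    if (n_test > 0L) {
      chosen <- with_local_seed(
        derive_seed(seed, match(cl, manifest$classes)),
        sample(pats, n_test)
      )
      test_ids <- c(test_ids, chosen)
    }
  }
  structure(
    list(
      train_patient_ids = sort(setdiff(names(pc), test_ids)),
      test_patient_ids = sort(test_ids),
      seed = as.integer(seed),
      test_fraction = test_fraction
    ),
    class = "split_assignment"
  )
}

#' Per-class test-count arithmetic of the stratified split
#'
#' Pure count computation used by [stratified_patient_split()]: the number of
#' test patients per class under the round-half-away-from-zero rule.
#'
#' @param class_counts named or unnamed integer vector of patients per class.
#' @param test_fraction fraction in (0, 1).
#' @return integer vector of test counts, same names as `class_counts`.
#' @export
#' @examples
#' split_test_counts(c(cancer = 168, hyper = 290, polyp = 276), 0.30)
split_test_counts <- function(class_counts, test_fraction) {
  stats::setNames(
    round_half_away(test_fraction * as.numeric(class_counts)),
    names(class_counts)
  )
}

#' Restrict a manifest to one side of a split
#'
#' @param manifest a `cohort_manifest`.
#' @param split a `split_assignment`.
#' @param side `"train"` or `"test"`.
#' @return a `cohort_manifest` containing only the selected patients.
#' @export
split_manifest <- function(manifest, split, side = c("train", "test")) {
  side <- match.arg(side)
  ids <- if (side == "train") split$train_patient_ids else split$test_patient_ids
  manifest_from_records(
    manifest$records[manifest$records$patient_id %in% ids, , drop = FALSE],
    manifest$classes
  )
}

#' Persist / restore a split assignment as JSON
#'
#' @param split a `split_assignment`.
#' @param path JSON file path.
#' @return `write_split` returns `path` invisibly; `read_split` the object.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(
      train_patient_ids = split$train_patient_ids,
      test_patient_ids = split$test_patient_ids,
      seed = split$seed,
      test_fraction = split$test_fraction
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      train_patient_ids = as.character(x$train_patient_ids),
      test_patient_ids = as.character(x$test_patient_ids),
      seed = as.integer(x$seed),
      test_fraction = x$test_fraction
    ),
    class = "split_assignment"
  )
}

#' Preprocessing configuration
#'
#' Defines the deterministic test-time path (center-crop to square, resize to
#' `target_size`, normalize by `(x - mean) / sd`) and the stochastic
#' training-time augmentations (random shifted crop, horizontal flip, and a
#' trivial-augment-style policy that applies one randomly chosen photometric
#' op at a random magnitude). The test path contains no stochastic op by
#' construction.
#'
#' @param target_size output side length in pixels.
#' @param mean,sd normalization constants on the `[0, 1]` intensity scale.
#' @param flip_prob probability of a horizontal flip (training only).
#' @param crop_pad_frac padding fraction for the random shifted crop.
#' @param policy photometric op names drawn from
#'   `c("identity", "brightness", "contrast", "gamma")`.
#' @param center_crop crop to the central square before resizing.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L, mean = 0.5, sd = 0.25,
                              flip_prob = 0.5, crop_pad_frac = 1 / 16,
                              policy = c("identity", "brightness", "contrast", "gamma"),
                              center_crop = TRUE) {
  if (target_size < 1L) stop("target_size must be positive")
  if (sd <= 0) stop("sd must be positive")
  structure(
    list(
      target_size = as.integer(target_size), mean = mean, sd = sd,
      flip_prob = flip_prob, crop_pad_frac = crop_pad_frac,
      policy = policy, center_crop = isTRUE(center_crop)
    ),
    class = "preprocess_config"
  )
}

apply_photometric <- function(img, op, mag) {
  switch(op,
    identity = img,
    brightness = clip01(img + mag * 0.3),
    contrast = clip01(0.5 + (img - 0.5) * (1 + mag * 0.8)),
    gamma = clip01(img^(2^(mag * 0.8))),
    stop("unknown augmentation op: ", op)
  )
}

#' Preprocess one image
#'
#' @param image a file path or a numeric matrix in `[0, 1]`.
#' @param config a [preprocess_config()].
#' @param mode `"test"` (deterministic: crop, resize, normalize) or
#'   `"train"` (adds random shifted crop, random flip, one random
#'   photometric op before normalizing). Training randomness is drawn from
#'   the current RNG state.
#' @return a `1 x target_size x target_size` array (channel first).
#' @export
preprocess_image <- function(image, config = preprocess_config(),
                             mode = c("test", "train")) {
  mode <- match.arg(mode)
  img <- if (is.character(image)) read_image(image) else image
  if (!is.matrix(img)) stop("image must decode to a single-channel matrix")

  if (config$center_crop && nrow(img) != ncol(img)) {
    s <- min(nrow(img), ncol(img))
    r0 <- (nrow(img) - s) %/% 2L
    c0 <- (ncol(img) - s) %/% 2L
    img <- img[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
  }
  ts <- config$target_size

  if (mode == "train") {
    pad <- max(0L, round(ts * config$crop_pad_frac))
    if (pad > 0L) {
      img <- resize_matrix(img, ts + 2L * pad)
      oy <- sample.int(2L * pad + 1L, 1L) - 1L
      ox <- sample.int(2L * pad + 1L, 1L) - 1L
      img <- img[(oy + 1L):(oy + ts), (ox + 1L):(ox + ts), drop = FALSE]
    } else {
      img <- resize_matrix(img, ts)
    }
    if (stats::runif(1) < config$flip_prob) {
      img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    }
    op <- sample(config$policy, 1L)
    mag <- stats::runif(1, -1, 1)
    img <- apply_photometric(img, op, mag)
  } else {
    img <- resize_matrix(img, ts)
  }
  out <- (img - config$mean) / config$sd
  array(out, dim = c(1L, ts, ts))
}
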