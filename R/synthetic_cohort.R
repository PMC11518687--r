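# Synthetic ultrasound-like cohort generator: known class structure, planted
# outliers, per-patient RNG streams for stable incremental generation.

#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of patients imaged in two views (longitudinal and
#' transverse), with three (or more) lesion classes whose appearance overlaps
#' by a controllable amount, multiplicative speckle noise, and an optional
#' fraction of planted outlier images.
#'
#' The appearance model is a bright ellipse (a proxy for the endometrial
#' stripe) over a dark fan-shaped scan sector, textured with a class-specific
#' spatial frequency and corrupted by Rayleigh-like multiplicative speckle
#' built from the squared mean of two smoothed Gaussian fields. Class
#' appearance parameters sit at a common base point displaced by
#' `separation` times a fixed per-class direction, so `separation = 0` makes
#' all classes identically distributed and larger values pull them apart.
#'
#' @param classes character vector of class names (>= 1).
#' @param n_patients_per_class integer vector (recycled) of patients per class.
#' @param images_per_patient integer range `c(lo, hi)`; each patient receives
#'   a uniform draw from `lo:hi` images. The default 2--4 gives roughly 2.5
#'   images per patient, matching a typical two-view acquisition.
#' @param image_size side length in pixels of the generated square images.
#' @param separation non-negative scalar scaling inter-class appearance
#'   distance; 0 means identical appearance distributions.
#' @param class_params optional named list (one entry per class) of lists with
#'   fields `axis_ratio`, `tex_freq`, `intensity`, `edge_soft`; defaults are
#'   derived from `separation`.
#' @param speckle_sigma non-negative multiplicative speckle scale.
#' @param outlier_fraction fraction in `[0, 1)` of images to corrupt.
#' @param outlier_modes subset of `c("blank", "blur", "occlude", "label_swap")`.
#' @param seed integer master seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(classes = c("cancer", "hyper", "polyp"),
                             n_patients_per_class = 12L,
                             images_per_patient = c(2L, 4L),
                             image_size = 64L,
                             separation = 1,
                             class_params = NULL,
                             speckle_sigma = 0.4,
                             outlier_fraction = 0,
                             outlier_modes = c("blank", "blur", "occlude", "label_swap"),
                             seed = 1L) {
  if (length(classes) < 1L) stop("at least one class is required")
  n_patients_per_class <- rep_len(as.integer(n_patients_per_class), length(classes))
  if (any(n_patients_per_class < 0L)) stop("patient counts must be >= 0")
  images_per_patient <- as.integer(images_per_patient)
  if (length(images_per_patient) != 2L || images_per_patient[1] > images_per_patient[2]) {
    stop("images_per_patient must be c(lo, hi) with lo <= hi")
  }
  if (images_per_patient[1] < 1L) stop("each patient needs at least one image")
  if (separation < 0) stop("separation must be >= 0")
  if (speckle_sigma < 0) stop("speckle_sigma must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be in [0, 1)")
  }
  outlier_modes <- match.arg(outlier_modes,
    c("blank", "blur", "occlude", "label_swap"),
    several.ok = TRUE
  )
  if (is.null(class_params)) {
    class_params <- default_class_params(classes, separation)
  }
  if (!all(classes %in% names(class_params))) {
    stop("class_params must be defined for every class")
  }
  structure(
    list(
      classes = classes,
      n_patients_per_class = n_patients_per_class,
      images_per_patient = images_per_patient,
      image_size = as.integer(image_size),
      separation = separation,
      class_params = class_params,
      speckle_sigma = speckle_sigma,
      outlier_fraction = outlier_fraction,
      outlier_modes = outlier_modes,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Class appearance = shared base point + separation * fixed direction on a
# circle in parameter space, so all pairwise appearance distances grow with
# `separation` and vanish at 0. Works for any number of classes.
default_class_params <- function(classes, separation) {
  k <- length(classes)
  params <- vector("list", k)
  names(params) <- classes
  for (i in seq_len(k)) {
    a <- 2 * pi * (i - 1) / max(k, 1L)
    params[[i]] <- list(
      axis_ratio = 0.55 + separation * 0.13 * cos(a),
      tex_freq   = 6 + separation * 2.6 * sin(a),
      intensity  = 0.60 + separation * 0.10 * cos(a + pi / 3),
      edge_soft  = 0.16 + separation * 0.06 * sin(a + pi / 3)
    )
  }
  params
}

# Render one lesion image. All randomness comes from the caller's RNG state.
render_lesion_image <- function(size, params, view, speckle_sigma) {
  ax <- seq(-1, 1, length.out = size)
  xg <- matrix(ax, size, size, byrow = TRUE)
  yg <- matrix(ax, size, size)

  # fan-shaped sector: apex above the top edge, opening downwards
  apex <- c(0, -1.35)
  dx <- xg - apex[1]
  dy <- yg - apex[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) # 0 points straight down
  fan <- (r < 2.25) & (abs(ang) < 65 * pi / 180)
  img <- ifelse(fan, 0.09 + 0.03 * (1 - r / 2.25), 0.02)

  # ellipse pose: jittered center/orientation; transverse view rotates 90 deg
  cx <- stats::runif(1, -0.12, 0.12)
  cy <- stats::runif(1, -0.02, 0.22)
  theta <- stats::runif(1, -0.25, 0.25) + if (view == "transverse") pi / 2 else 0
  a_len <- 0.45 * stats::runif(1, 0.9, 1.1)
  b_len <- a_len * max(params$axis_ratio, 0.12)
  u <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  v <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  q <- (u / a_len)^2 + (v / b_len)^2
  edge <- max(params$edge_soft, 0.02)
  lesion <- 1 / (1 + exp((q - 1) / edge)) # soft ellipse boundary

  # banded internal texture with class-specific spatial frequency
  phase <- stats::runif(1, 0, 2 * pi)
  freq <- max(params$tex_freq, 0.5)
  tex <- 0.5 + 0.5 * sin(2 * pi * freq * (u + 0.25 * sin(2 * pi * v)) + phase)
  inten <- clip01(params$intensity)
  img <- img + lesion * (inten - img) + lesion * 0.10 * (tex - 0.5)

  if (speckle_sigma > 0) {
    g1 <- matrix(stats::rnorm(size * size), size, size)
    g2 <- matrix(stats::rnorm(size * size), size, size)
    sig <- max(size / 48, 0.8)
    g1 <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(g1), sigma = sig)))
    g2 <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(g2), sigma = sig)))
    spk <- g1^2 + g2^2
    spk <- spk / mean(spk)
    img <- img * (1 + speckle_sigma * (spk - 1))
  }
  clip01(img)
}

apply_outlier_mode <- function(img, mode) {
  size <- nrow(img)
  switch(mode,
    blank = matrix(0.08, size, size),
    blur = as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = size / 8)
    )),
    occlude = {
      # dark rectangle covering at least 25% of the area
      w <- sample(seq(ceiling(size * 0.5), size), 1L)
      h <- max(ceiling(size * size * 0.25 / w), ceiling(size * 0.3))
      x0 <- sample(seq_len(size - w + 1L), 1L)
      y0 <- sample(seq_len(size - h + 1L), 1L)
      img[y0:(y0 + h - 1L), x0:(x0 + w - 1L)] <- 0.02
      img
    },
    stop("unknown outlier mode: ", mode)
  )
}

#' Generate a synthetic cohort on disk
#'
#' Writes one 8-bit grayscale PNG per image plus a CSV manifest
#' (`manifest.csv`, columns `image_id, patient_id, class, view, path,
#' is_outlier`) under `out_dir`. Each patient draws its image count from the
#' configured range; when a patient has two or more images both views are
#' present. Exactly `round(outlier_fraction * n_images)` images are corrupted
#' using the configured modes, and recorded in the returned ground truth.
#'
#' Each patient owns an RNG stream keyed by (seed, patient index), so
#' enlarging the cohort never perturbs previously generated patients, and the
#' same config and seed reproduce byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if missing).
#' @return a list with elements `manifest` (a validated manifest, see
#'   [load_manifest()]) and `ground_truth` (list with `planted_outlier_ids`,
#'   `outlier_modes`, `true_class`, `view`).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  classes <- config$classes
  size <- config$image_size
  records <- list()
  images <- list()
  patient_idx <- 0L

  for (ci in seq_along(classes)) {
    for (p in seq_len(config$n_patients_per_class[ci])) {
      patient_idx <- patient_idx + 1L
      pid <- sprintf("pt%04d", patient_idx)
      pseed <- derive_seed(config$seed, 1000L + patient_idx)
      imgs <- with_local_seed(pseed, {
        n_img <- sample(seq(config$images_per_patient[1], config$images_per_patient[2]), 1L)
        views <- rep(c("longitudinal", "transverse"), length.out = n_img)
        lapply(seq_len(n_img), function(j) {
          list(
            view = views[j],
            img = render_lesion_image(
              size, config$class_params[[classes[ci]]],
              views[j], config$speckle_sigma
            )
          )
        })
      })
      for (j in seq_along(imgs)) {
        iid <- sprintf("%s_img%02d", pid, j)
        records[[length(records) + 1L]] <- data.frame(
          image_id = iid, patient_id = pid, class = classes[ci],
          view = imgs[[j]]$view, path = file.path("images", paste0(iid, ".png")),
          is_outlier = FALSE, stringsAsFactors = FALSE
        )
        images[[iid]] <- imgs[[j]]$img
      }
    }
  }
  if (length(records) == 0L) stop("configuration generates an empty cohort")
  tab <- do.call(rbind, records)

  # plant outliers: selection from a dedicated stream, corruption from
  # per-image streams so the plan is stable under cohort growth
  n_img <- nrow(tab)
  n_out <- round_half_away(config$outlier_fraction * n_img)
  outlier_ids <- character(0)
  outlier_modes <- character(0)
  if (n_out > 0L) {
    sel <- with_local_seed(
      derive_seed(config$seed, 900000L),
      sample(n_img, n_out)
    )
    modes <- rep_len(config$outlier_modes, n_out)
    for (m in seq_along(sel)) {
      i <- sel[m]
      iid <- tab$image_id[i]
      mode <- modes[m]
      iseed <- derive_seed(config$seed, 910000L + i)
      if (mode == "label_swap") {
        # regenerate from another class's appearance, keep the patient label
        other <- setdiff(classes, tab$class[i])
        if (length(other) == 0L) next
        images[[iid]] <- with_local_seed(iseed, {
          src <- sample(other, 1L)
          render_lesion_image(
            size, config$class_params[[src]],
            tab$view[i], config$speckle_sigma
          )
        })
      } else {
        images[[iid]] <- with_local_seed(
          iseed,
          apply_outlier_mode(images[[iid]], mode)
        )
      }
      tab$is_outlier[i] <- TRUE
      outlier_ids <- c(outlier_ids, iid)
      outlier_modes <- c(outlier_modes, mode)
    }
  }

  for (iid in tab$image_id) {
    png::writePNG(images[[iid]], file.path(out_dir, "images", paste0(iid, ".png")))
  }
  utils::write.csv(tab, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  truth <- list(
    planted_outlier_ids = outlier_ids,
    outlier_modes = stats::setNames(outlier_modes, outlier_ids),
    true_class = stats::setNames(
      tab$class[!duplicated(tab$patient_id)],
      tab$patient_id[!duplicated(tab$patient_id)]
    ),
    view = stats::setNames(tab$view, tab$image_id)
  )
  list(
    manifest = load_manifest(file.path(out_dir, "manifest.csv"), classes = classes),
    ground_truth = truth
  )
}

#' Between/within-class separability of a cohort
#'
#' A distribution-level contrast on raw-pixel features: the mean squared
#' distance between images of different classes divided by the mean squared
#' distance between images of the same class, computed from per-class means
#' and total within-class variance. Both terms are functionals of the
#' per-class empirical distributions, so the ratio is exactly invariant to
#' duplicating images and tends to 1 when classes are identically
#' distributed.
#'
#' @param manifest a manifest whose images exist on disk.
#' @param sample_px images are downsampled to `sample_px` x `sample_px`
#'   before computing distances.
#' @return a single non-negative number; 1 means no separation.
#' @export
class_separability <- function(manifest, sample_px = 16L) {
  records <- manifest$records
  classes <- unique(records$class)
  if (length(classes) < 2L) stop("separability needs at least two classes")
  feats <- t(vapply(records$path, function(p) {
    as.numeric(resize_matrix(read_image(p), sample_px))
  }, numeric(sample_px^2)))

  mu <- list()
  vr <- numeric(length(classes))
  names(vr) <- classes
  for (cl in classes) {
    xc <- feats[records$class == cl, , drop = FALSE]
    mu[[cl]] <- colMeans(xc)
    vr[cl] <- mean(rowSums(sweep(xc, 2L, mu[[cl]])^2))
  }
  within <- mean(2 * vr) # E||X - X'||^2 for iid X, X' within a class
  between <- 0
  n_pairs <- 0
  for (a in seq_along(classes)) {
    for (b in seq_along(classes)) {
      if (a < b) {
        ca <- classes[a]
        cb <- classes[b]
        between <- between + sum((mu[[ca]] - mu[[cb]])^2) + vr[ca] + vr[cb]
        n_pairs <- n_pairs + 1
      }
    }
  }
  (between / n_pairs) / within
}
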