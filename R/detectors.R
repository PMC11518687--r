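# Anomaly detectors over feature vectors. Isolation Forest and Local Outlier
# Factor are implemented here (no suitable package in the dependency set);
# the One-Class SVM is fit through e1071. All three are reduced to a common
# contract: a score per point, thresholded by rank so that exactly
# round(contamination * N) points are flagged.

# --- Isolation Forest -------------------------------------------------------

# Average unsuccessful-search path length of a BST with n points.
avg_path_length <- function(n) {
  ifelse(n <= 1, 0, 2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n)
}

# Grow one isolation tree on rows `idx` of X; returns a nested list.
grow_itree <- function(x, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1L || depth >= max_depth) {
    return(list(size = n))
  }
  # random attribute with spread; give up if every column is constant
  cols <- sample.int(ncol(x), ncol(x))
  for (j in cols) {
    v <- x[idx, j]
    lo <- min(v)
    hi <- max(v)
    if (hi > lo) {
      s <- stats::runif(1, lo, hi)
      left <- idx[v < s]
      right <- idx[v >= s]
      return(list(
        attr = j, split = s,
        left = grow_itree(x, left, depth + 1L, max_depth),
        right = grow_itree(x, right, depth + 1L, max_depth)
      ))
    }
  }
  list(size = n)
}

# Path length of every row of X in one tree (iterative partition descent).
itree_depths <- function(tree, x) {
  depths <- numeric(nrow(x))
  recurse <- function(node, rows, depth) {
    if (is.null(node$attr)) {
      depths[rows] <<- depth + avg_path_length(node$size)
      return(invisible())
    }
    go_left <- x[rows, node$attr] < node$split
    if (any(go_left)) recurse(node$left, rows[go_left], depth + 1)
    if (any(!go_left)) recurse(node$right, rows[!go_left], depth + 1)
  }
  recurse(tree, seq_len(nrow(x)), 0)
  depths
}

#' Isolation Forest anomaly scores
#'
#' Scores in `(0, 1)`; larger means more anomalous. A forest of random
#' binary-split trees is grown on subsamples; the score of a point is
#' `2^(-E[h] / c(psi))` where `E[h]` is its mean path length and `c(psi)`
#' the expected path length at the subsample size.
#'
#' @param x numeric matrix (rows = points).
#' @param n_trees number of trees.
#' @param sample_size subsample size per tree (capped at `nrow(x)`).
#' @param seed integer seed; scores are deterministic given it.
#' @return numeric vector of length `nrow(x)`.
#' @export
isolation_forest_score <- function(x, n_trees = 100L, sample_size = 256L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(sample_size, n)
  max_depth <- ceiling(log2(max(psi, 2L)))
  depths <- with_local_seed(seed, {
    d <- matrix(0, n, n_trees)
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, psi)
      tree <- grow_itree(x, idx, 0L, max_depth)
      d[, t] <- itree_depths(tree, x)
    }
    d
  })
  2^(-rowMeans(depths) / avg_path_length(psi))
}

# --- Local Outlier Factor ---------------------------------------------------

#' Local Outlier Factor scores
#'
#' Classic LOF with a k-nearest-neighbour neighbourhood (ties broken by row
#' index). Scores near 1 indicate inliers; larger values indicate points in
#' sparser regions than their neighbours. Zero distances (duplicated or
#' fully degenerate inputs) are floored at a small epsilon so local
#' reachability densities stay finite; fully identical inputs therefore give
#' all points the same score.
#'
#' @param x numeric matrix (rows = points).
#' @param k neighbourhood size (capped at `nrow(x) - 1`).
#' @return numeric vector of length `nrow(x)`.
#' @export
lof_score <- function(x, k = 20L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) {
    return(rep(1, n))
  }
  k <- max(1L, min(k, n - 1L))
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # k nearest neighbours per point, deterministic tie-break by index
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  kdist <- d[cbind(seq_len(n), nn[, k])]
  eps <- 1e-12
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nn[i, ]], d[i, nn[i, ]])
    lrd[i] <- 1 / max(mean(reach), eps)
  }
  vapply(seq_len(n), function(i) mean(lrd[nn[i, ]]) / lrd[i], numeric(1))
}

# --- Common detector interface ---------------------------------------------

#' Detector configuration
#'
#' @param method one of `"isolation_forest"`, `"local_outlier_factor"`,
#'   `"one_class_svm"`.
#' @param contamination expected outlier fraction in `[0, 0.5)`; exactly
#'   `round(contamination * N)` points are flagged by score rank.
#' @param seed integer seed for stochastic detectors.
#' @param ... method-specific parameters: `n_trees`, `sample_size`
#'   (isolation forest); `k` (LOF); `nu`, `gamma` (one-class SVM).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(method = c(
                              "isolation_forest", "local_outlier_factor",
                              "one_class_svm"
                            ),
                            contamination = 0.05, seed = 1L, ...) {
  method <- match.arg(method)
  if (contamination < 0 || contamination >= 0.5) {
    stop("contamination must be in [0, 0.5)")
  }
  structure(
    list(
      method = method, contamination = contamination,
      seed = as.integer(seed), params = list(...)
    ),
    class = "detector_config"
  )
}

# Anomaly score under one detector config (internal; higher = more anomalous).
detector_scores <- function(x, config) {
  p <- config$params
  switch(config$method,
    isolation_forest = isolation_forest_score(
      x,
      n_trees = p$n_trees %||% 100L,
      sample_size = p$sample_size %||% 256L,
      seed = config$seed
    ),
    local_outlier_factor = lof_score(x, k = p$k %||% 20L),
    one_class_svm = {
      # soft boundary (nu well above the contamination) so gross outliers
      # stay outside it; the rank threshold picks the flag count anyway
      fit <- tryCatch(
        e1071::svm(
          x,
          type = "one-classification", kernel = "radial",
          nu = p$nu %||% 0.5,
          gamma = p$gamma %||% (0.35 / ncol(x)), scale = FALSE
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        rep(0, nrow(x)) # degenerate input: all scores tie
      } else {
        pred <- predict(fit, x, decision.values = TRUE)
        -attr(pred, "decision.values")[, 1]
      }
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag outliers in a feature matrix
#'
#' Computes the configured detector's anomaly score for every row and flags
#' the `round(contamination * N)` highest-scoring rows (rank threshold, ties
#' broken by row index), so the flagged fraction matches the contamination
#' exactly. Deterministic given the config seed.
#'
#' @param features a `feature_matrix` (see [kfold_feature_extraction()]) or a
#'   plain numeric matrix.
#' @param config a [detector_config()].
#' @return logical vector, `TRUE` = flagged outlier, named by image id when
#'   available.
#' @export
detect_outliers <- function(features, config) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  ids <- if (inherits(features, "feature_matrix")) features$image_ids else rownames(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 points for outlier detection")
  n_flag <- round_half_away(config$contamination * n)
  mask <- rep(FALSE, n)
  if (n_flag > 0L) {
    score <- detector_scores(x, config)
    mask[order(-score, seq_len(n))[seq_len(n_flag)]] <- TRUE
  }
  if (!is.null(ids)) names(mask) <- ids
  mask
}
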