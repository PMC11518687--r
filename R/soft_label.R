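# Cluster-distance soft labels: dimension reduction, class centroids,
# inverse-distance-ratio weights, temperature, renormalization.

#' Soft-label configuration
#'
#' @param tau temperature, a non-negative scalar controlling how much target
#'   mass moves off the true class: `tau = 0` reproduces one-hot labels; the
#'   experiment grid of interest is `c(0.6, 0.7, 0.8, 0.9)`.
#' @param reduce_dim target dimension of the reducer (>= 2).
#' @param reducer `"linear_projection"` (deterministic top principal
#'   directions fit on the cleaned training features) or `"none"`.
#' @param distance metric in the reduced space; only `"euclidean"` is
#'   implemented.
#' @param epsilon positive floor applied to distances before inversion; when
#'   `NULL`, `1e-6` times the median inter-centroid distance is used.
#' @return an object of class `soft_label_config`.
#' @export
soft_label_config <- function(tau = 0.7, reduce_dim = 8L,
                              reducer = c("linear_projection", "none"),
                              distance = "euclidean", epsilon = NULL) {
  if (tau < 0) stop("tau must be >= 0")
  reducer <- match.arg(reducer)
  if (!identical(distance, "euclidean")) stop("only euclidean distance is implemented")
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  structure(
    list(
      tau = tau, reduce_dim = as.integer(reduce_dim),
      reducer = reducer, distance = distance, epsilon = epsilon
    ),
    class = "soft_label_config"
  )
}

#' Fit the reducer and per-class centroids
#'
#' Clustering is class-conditional: each class contributes one cluster whose
#' center is the mean of that class's (reduced) feature vectors. The linear
#' reducer is fit on the cleaned training features only, by top principal
#' directions with a deterministic sign convention, so targets are exactly
#' reproducible.
#'
#' @param features a `feature_matrix` or plain matrix with rownames.
#' @param labels class label per row (character).
#' @param config a [soft_label_config()].
#' @return an object of class `cluster_model`: list with `centroids`
#'   (K x d' matrix, rownames = class order), `center`, `rotation` (NULL for
#'   `reducer = "none"`), `classes`, `epsilon`.
#' @export
fit_cluster_model <- function(features, labels, config = soft_label_config()) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  if (nrow(x) != length(labels)) stop("labels must match feature rows")
  classes <- sort(unique(labels))
  if (any(table(labels) < 1L)) stop("every class needs at least one sample")

  center <- NULL
  rotation <- NULL
  if (config$reducer == "linear_projection") {
    d <- min(config$reduce_dim, nrow(x) - 1L, ncol(x))
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
    rotation <- pr$rotation
    for (j in seq_len(ncol(rotation))) {
      peak <- which.max(abs(rotation[, j]))
      if (rotation[peak, j] < 0) rotation[, j] <- -rotation[, j]
    }
    center <- pr$center
    x <- sweep(x, 2L, center) %*% rotation
  }
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  if (!all(is.finite(centroids))) stop("non-finite centroid; check input features")

  eps <- config$epsilon
  if (is.null(eps)) {
    dc <- stats::dist(centroids)
    med <- stats::median(dc)
    eps <- if (is.finite(med) && med > 0) 1e-6 * med else 1e-6
  }
  structure(
    list(
      centroids = centroids, center = center, rotation = rotation,
      classes = classes, epsilon = eps
    ),
    class = "cluster_model"
  )
}

# Apply the fitted reducer to new feature rows.
reduce_features <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(model$rotation)) {
    return(x)
  }
  sweep(x, 2L, model$center) %*% model$rotation
}

#' Inverse-distance class weights
#'
#' For a reduced vector with distances `d_c` to the class centroids, the
#' weight of class `c` is `(1 / max(d_c, eps)) / sum_j (1 / max(d_j, eps))`:
#' a row-stochastic vector that decreases strictly in `d_c` with the other
#' distances held fixed.
#'
#' @param x one reduced vector, or a matrix of rows already in the model's
#'   reduced space.
#' @param model a [fit_cluster_model()] result.
#' @param epsilon distance floor; defaults to the model's.
#' @return an N x K row-stochastic matrix (a single row for vector input).
#' @export
inverse_distance_weights <- function(x, model, epsilon = model$epsilon) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (!all(is.finite(x))) stop("x must be finite")
  k <- nrow(model$centroids)
  d2 <- outer(rowSums(x^2), rep(1, k)) -
    2 * x %*% t(model$centroids) +
    outer(rep(1, nrow(x)), rowSums(model$centroids^2))
  d <- sqrt(pmax(d2, 0))
  inv <- 1 / pmax(d, epsilon)
  w <- inv / rowSums(inv)
  colnames(w) <- rownames(model$centroids)
  w
}

#' Soften hard labels with temperature tau
#'
#' The target for image i and class c is
#' `(onehot_ic + tau * w_ic) / (1 + tau)`: the hard label plus the
#' tau-scaled inverse-distance weight, renormalized so every row is a
#' probability distribution. `tau = 0` reproduces one-hot targets exactly,
#' and for `tau <= 1` the argmax of every row stays on the hard label.
#'
#' @param hard_labels character (or factor) vector of true classes.
#' @param weights N x K row-stochastic matrix, columns ordered/named by class.
#' @param tau non-negative temperature.
#' @param classes class order; defaults to `colnames(weights)`.
#' @return an object of class `soft_label_matrix`: list with `image_ids`,
#'   `targets` (N x K row-stochastic matrix), `tau`, `classes`.
#' @export
soften_labels <- function(hard_labels, weights, tau, classes = colnames(weights)) {
  if (tau < 0) stop("tau must be >= 0")
  weights <- as.matrix(weights)
  if (is.null(classes)) stop("class order undefined: name the weight columns or pass classes")
  hard_labels <- as.character(hard_labels)
  if (nrow(weights) != length(hard_labels)) stop("weights rows must match labels")
  idx <- match(hard_labels, classes)
  if (anyNA(idx)) stop("hard label outside the class set")
  if (any(abs(rowSums(weights) - 1) > 1e-6)) stop("weights must be row-stochastic")
  targets <- (one_hot(idx, length(classes)) + tau * weights) / (1 + tau)
  colnames(targets) <- classes
  rownames(targets) <- rownames(weights)
  structure(
    list(
      image_ids = rownames(weights), targets = targets,
      tau = tau, classes = classes
    ),
    class = "soft_label_matrix"
  )
}

#' Build the softened training set
#'
#' Composition of [fit_cluster_model()], [inverse_distance_weights()] and
#' [soften_labels()] over a cleaned training manifest and its features.
#'
#' @param cleaned_manifest cleaned training `cohort_manifest`.
#' @param features a `feature_matrix` covering (at least) the manifest.
#' @param config a [soft_label_config()].
#' @return list with `soft_labels` (a `soft_label_matrix` aligned to the
#'   manifest's images) and `model` (the `cluster_model`).
#' @export
build_softened_set <- function(cleaned_manifest, features, config = soft_label_config()) {
  records <- cleaned_manifest$records
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  if (!all(records$image_id %in% rownames(x))) {
    stop("features do not cover the cleaned manifest")
  }
  x <- x[records$image_id, , drop = FALSE]
  model <- fit_cluster_model(x, records$class, config)
  w <- inverse_distance_weights(reduce_features(model, x), model)
  rownames(w) <- records$image_id
  soft <- soften_labels(records$class, w, config$tau, classes = model$classes)
  list(soft_labels = soft, model = model)
}

#' Persist a soft-label matrix as CSV
#'
#' Columns: `image_id`, one target column per class (`t_<class>`), `tau`.
#'
#' @param soft a `soft_label_matrix`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_soft_labels <- function(soft, path) {
  tab <- data.frame(image_id = soft$image_ids, stringsAsFactors = FALSE)
  for (cl in soft$classes) tab[[paste0("t_", cl)]] <- soft$targets[, cl]
  tab$tau <- soft$tau
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a soft-label matrix written by [write_soft_labels()]
#'
#' @param path CSV file path.
#' @return a `soft_label_matrix`.
#' @export
read_soft_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cls <- sub("^t_", "", grep("^t_", names(tab), value = TRUE))
  targets <- as.matrix(tab[, paste0("t_", cls), drop = FALSE])
  colnames(targets) <- cls
  rownames(targets) <- tab$image_id
  structure(
    list(
      image_ids = tab$image_id, targets = targets,
      tau = tab$tau[1], classes = cls
    ),
    class = "soft_label_matrix"
  )
}
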