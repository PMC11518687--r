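# Soft-target classifier training. Two compact reference architectures are
# implemented natively (a one-hidden-layer MLP and a one-conv-layer CNN)
# with AdamW and log-softmax outputs; heavyweight backbone names are
# registry entries a user can bind to an external implementation.

.heavy_backbones <- c(
  "resnet50", "densenet169", "densenet201",
  "vgg16_bn", "efficientnet_b4", "vit_b"
)

#' Model specification
#'
#' @param architecture registry name. `"tiny_mlp"` (default) and
#'   `"tiny_cnn"` are implemented natively; the heavyweight names
#'   (`"resnet50"`, `"densenet169"`, `"densenet201"`, `"vgg16_bn"`,
#'   `"efficientnet_b4"`, `"vit_b"`) are accepted as pluggable entries and
#'   must be bound with [register_architecture()] before training.
#' @param n_classes number of output classes (>= 2).
#' @param input_size model input side length in pixels; images are
#'   preprocessed to this size.
#' @param hidden hidden width (tiny_mlp) / dense input taken from pooling
#'   (tiny_cnn ignores this).
#' @param n_filters convolution filters (tiny_cnn).
#' @param pretrained request pretrained weights (only meaningful for
#'   user-registered backbones; the native networks train from scratch).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(architecture = "tiny_mlp", n_classes = 3L,
                       input_size = 16L, hidden = 32L, n_filters = 8L,
                       pretrained = FALSE) {
  known <- c("tiny_mlp", "tiny_cnn", .heavy_backbones, names(.sonoclean_env$arch_registry))
  if (!architecture %in% known) {
    stop(
      "unknown architecture '", architecture, "'; known: ",
      paste(unique(known), collapse = ", ")
    )
  }
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (architecture == "tiny_cnn" && (input_size - 2L) %% 2L != 0L) {
    stop("tiny_cnn needs an even input_size so pooling divides the feature map")
  }
  structure(
    list(
      architecture = architecture, n_classes = as.integer(n_classes),
      input_size = as.integer(input_size), hidden = as.integer(hidden),
      n_filters = as.integer(n_filters), pretrained = isTRUE(pretrained)
    ),
    class = "model_spec"
  )
}

#' Register a custom architecture
#'
#' Binds a name to a list of functions `init(spec, seed)`,
#' `forward(params, x)` (returning row-wise log-probabilities),
#' `backward(params, cache, dz)` and optionally `hidden(params, x)`. This is
#' the hook through which heavyweight pretrained backbones can be plugged in
#' without changing any pipeline code.
#'
#' @param name architecture name.
#' @param impl list of functions as described.
#' @return invisibly, `name`.
#' @export
register_architecture <- function(name, impl) {
  reg <- .sonoclean_env$arch_registry
  if (is.null(reg)) reg <- list()
  reg[[name]] <- impl
  .sonoclean_env$arch_registry <- reg
  invisible(name)
}

arch_impl <- function(spec) {
  reg <- .sonoclean_env$arch_registry
  if (!is.null(reg[[spec$architecture]])) {
    return(reg[[spec$architecture]])
  }
  switch(spec$architecture,
    tiny_mlp = mlp_impl(),
    tiny_cnn = cnn_impl(),
    stop(
      "architecture '", spec$architecture, "' is a pluggable backbone name; ",
      "bind an implementation with register_architecture() before training"
    )
  )
}

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay (applied to weights, not
#'   biases).
#' @param beta1,beta2,adam_eps AdamW moment constants.
#' @param seed integer seed; fixes init, shuffling and augmentation draws.
#' @param augment apply training-time augmentations each epoch (see
#'   [preprocess_image()]); off by default for the compact networks.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = 32L, lr = 5e-3,
                         weight_decay = 1e-2, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L, augment = FALSE) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be positive")
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
      adam_eps = adam_eps, seed = as.integer(seed), augment = isTRUE(augment)
    ),
    class = "train_config"
  )
}

#' Mean soft-target cross-entropy
#'
#' `mean_i( -sum_c targets[i, c] * log_probs[i, c] )`. Reduces to the usual
#' cross-entropy when the targets are one-hot, and is bounded below by the
#' mean entropy of the target rows.
#'
#' @param log_probs N x K matrix of row-wise log-probabilities.
#' @param targets N x K row-stochastic target matrix (or a
#'   `soft_label_matrix`).
#' @return a single number.
#' @export
soft_cross_entropy <- function(log_probs, targets) {
  if (inherits(targets, "soft_label_matrix")) targets <- targets$targets
  targets <- as.matrix(targets)
  if (!all(dim(log_probs) == dim(targets))) stop("shape mismatch")
  if (any(abs(rowSums(targets) - 1) > 1e-6) || any(targets < -1e-12)) {
    stop("targets must be row-stochastic")
  }
  mean(-rowSums(targets * log_probs))
}

# --- tiny_mlp ---------------------------------------------------------------

mlp_impl <- function() {
  list(
    init = function(spec, seed) {
      d <- spec$input_size^2
      h <- spec$hidden
      k <- spec$n_classes
      with_local_seed(seed, list(
        w1 = matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h),
        b1 = rep(0, h),
        w2 = matrix(stats::rnorm(h * k, 0, sqrt(2 / h)), h, k),
        b2 = rep(0, k)
      ))
    },
    forward = function(params, x) {
      h <- pmax(x %*% params$w1 + rep(params$b1, each = nrow(x)), 0)
      z <- h %*% params$w2 + rep(params$b2, each = nrow(x))
      list(log_probs = log_softmax(z), cache = list(x = x, h = h))
    },
    backward = function(params, cache, dz) {
      dh <- (dz %*% t(params$w2)) * (cache$h > 0)
      list(
        w2 = t(cache$h) %*% dz, b2 = colSums(dz),
        w1 = t(cache$x) %*% dh, b1 = colSums(dh)
      )
    },
    hidden = function(params, x) {
      pmax(x %*% params$w1 + rep(params$b1, each = nrow(x)), 0)
    },
    decay = c(w1 = TRUE, b1 = FALSE, w2 = TRUE, b2 = FALSE)
  )
}

# --- tiny_cnn ---------------------------------------------------------------

# Precompute im2col gather indices for a 3x3 valid convolution on s x s.
conv_indices <- function(s) {
  m <- s - 2L
  pix <- as.vector(outer(seq_len(m), seq_len(m), function(r, c) (c - 1L) * s + r))
  offs <- as.vector(outer(0:2, 0:2, function(dr, dc) dc * s + dr))
  idx <- outer(pix, offs, `+`) # m^2 x 9 indices into a column-major s x s image
  # 2x2 mean-pool gather: p^2 x 4 indices into the m x m map
  p <- m %/% 2L
  base <- as.vector(outer(seq(1L, m, by = 2L), seq(1L, m, by = 2L),
    function(r, c) (c - 1L) * m + r
  ))
  pool <- cbind(base, base + 1L, base + m, base + m + 1L)
  list(conv = idx, pool = pool, m = m, p = p)
}

cnn_impl <- function() {
  list(
    init = function(spec, seed) {
      f <- spec$n_filters
      k <- spec$n_classes
      p <- (spec$input_size - 2L) %/% 2L
      with_local_seed(seed, list(
        wc = matrix(stats::rnorm(9 * f, 0, sqrt(2 / 9)), 9, f),
        bc = rep(0, f),
        w2 = matrix(stats::rnorm(p * p * f * k, 0, sqrt(2 / (p * p * f))), p * p * f, k),
        b2 = rep(0, k),
        geom = conv_indices(spec$input_size)
      ))
    },
    forward = function(params, x) {
      g <- params$geom
      n <- nrow(x)
      f <- ncol(params$wc)
      # im2col: one (n*m^2) x 9 gather, then a single GEMM for all filters
      cols <- x[, as.vector(g$conv), drop = FALSE]
      dim(cols) <- c(n * g$m^2, 9L)
      conv <- cols %*% params$wc + rep(params$bc, each = n * g$m^2)
      act <- array(pmax(conv, 0), c(n, g$m^2, f))
      pooled <- (act[, g$pool[, 1], , drop = FALSE] + act[, g$pool[, 2], , drop = FALSE] +
        act[, g$pool[, 3], , drop = FALSE] + act[, g$pool[, 4], , drop = FALSE]) / 4
      flat <- matrix(pooled, n, g$p^2 * f)
      z <- flat %*% params$w2 + rep(params$b2, each = n)
      list(
        log_probs = log_softmax(z),
        cache = list(cols = cols, conv = conv, flat = flat)
      )
    },
    backward = function(params, cache, dz) {
      g <- params$geom
      n <- nrow(dz)
      f <- ncol(params$wc)
      dflat <- dz %*% t(params$w2)
      dpool <- array(dflat, c(n, g$p^2, f)) / 4
      dact <- array(0, c(n, g$m^2, f))
      for (q in 1:4) {
        dact[, g$pool[, q], ] <- dact[, g$pool[, q], , drop = FALSE] + dpool
      }
      dconv <- matrix(dact, n * g$m^2, f) * (cache$conv > 0)
      list(
        wc = crossprod(cache$cols, dconv), bc = colSums(dconv),
        w2 = t(cache$flat) %*% dz, b2 = colSums(dz)
      )
    },
    hidden = function(params, x) {
      # pooled conv activations as the embedding
      g <- params$geom
      n <- nrow(x)
      f <- ncol(params$wc)
      cols <- x[, as.vector(g$conv), drop = FALSE]
      dim(cols) <- c(n * g$m^2, 9L)
      act <- array(pmax(cols %*% params$wc + rep(params$bc, each = n * g$m^2), 0),
        c(n, g$m^2, f)
      )
      pooled <- (act[, g$pool[, 1], , drop = FALSE] + act[, g$pool[, 2], , drop = FALSE] +
        act[, g$pool[, 3], , drop = FALSE] + act[, g$pool[, 4], , drop = FALSE]) / 4
      matrix(pooled, n, g$p^2 * f)
    },
    decay = c(wc = TRUE, bc = FALSE, w2 = TRUE, b2 = FALSE)
  )
}

# --- AdamW optimizer over a named parameter list ---------------------------

adamw_step <- function(params, grads, state, config, step, decay_map) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- config$beta1 * state$m[[nm]] + (1 - config$beta1) * g
    state$v[[nm]] <- config$beta2 * state$v[[nm]] + (1 - config$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - config$beta1^step)
    vhat <- state$v[[nm]] / (1 - config$beta2^step)
    wd <- if (isTRUE(decay_map[[nm]])) config$weight_decay else 0
    params[[nm]] <- params[[nm]] -
      config$lr * (mhat / (sqrt(vhat) + config$adam_eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}

# Core optimizer loop on an already-featurized design matrix.
train_network <- function(x, targets, spec, config) {
  impl <- arch_impl(spec)
  params <- impl$init(spec, config$seed)
  state <- list(m = list(), v = list())
  n <- nrow(x)
  history <- numeric(config$epochs)
  step <- 0L
  decay_map <- as.list(impl$decay)
  with_local_seed(derive_seed(config$seed, 777L), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- perm[start:min(start + config$batch_size - 1L, n)]
        xb <- x[rows, , drop = FALSE]
        tb <- targets[rows, , drop = FALSE]
        fw <- impl$forward(params, xb)
        losses <- c(losses, soft_cross_entropy(fw$log_probs, tb))
        dz <- (exp(fw$log_probs) - tb) / nrow(xb)
        grads <- impl$backward(params, fw$cache, dz)
        step <- step + 1L
        upd <- adamw_step(params, grads, state, config, step, decay_map)
        params <- upd$params
        state <- upd$state
      }
      history[ep] <- mean(losses)
    }
  })
  structure(
    list(params = params, spec = spec, history = history, config = config),
    class = "network_fit"
  )
}

network_log_probs <- function(fit, x) {
  arch_impl(fit$spec)$forward(fit$params, x)$log_probs
}

network_hidden <- function(fit, x) {
  arch_impl(fit$spec)$hidden(fit$params, x)
}

# Featurize a manifest's images into the model's flattened input space.
# Test mode is deterministic; train mode draws augmentations from the
# current RNG state.
featurize_manifest <- function(manifest, input_size, preprocess = NULL,
                               mode = "test", images = NULL) {
  if (is.null(preprocess)) {
    preprocess <- preprocess_config(
      target_size = input_size,
      flip_prob = if (mode == "train") 0.5 else 0
    )
  }
  records <- manifest$records
  if (is.null(images)) {
    images <- lapply(records$path, read_image)
  }
  x <- t(vapply(images, function(m) {
    as.numeric(preprocess_image(m, preprocess, mode))
  }, numeric(preprocess$target_size^2)))
  rownames(x) <- records$image_id
  x
}

#' Train a classifier on (possibly softened) targets
#'
#' End-to-end training of a registry architecture on a manifest's images
#' with row-stochastic targets: log-softmax outputs, soft-target
#' cross-entropy loss, AdamW optimizer. One-hot targets are built from the
#' manifest when `targets` is `NULL`, so the same entry point covers
#' baseline (hard-label) and softened training.
#'
#' @param manifest training `cohort_manifest`.
#' @param targets a `soft_label_matrix`, an N x K matrix with rownames =
#'   image ids, or `NULL` for one-hot targets.
#' @param spec a [model_spec()].
#' @param config a [train_config()].
#' @param tag model tag recorded in prediction tables.
#' @return an object of class `trained_model` with fields `fit` (weights +
#'   per-epoch loss history), `spec`, `classes`, `tag`.
#' @export
train_classifier <- function(manifest, targets = NULL, spec = model_spec(),
                             config = train_config(), tag = spec$architecture) {
  records <- manifest$records
  if (nrow(records) == 0L) stop("empty training manifest")
  classes <- manifest$classes
  if (is.null(targets)) {
    tmat <- one_hot(match(records$class, classes), length(classes))
    colnames(tmat) <- classes
    rownames(tmat) <- records$image_id
  } else {
    if (inherits(targets, "soft_label_matrix")) targets <- targets$targets
    tmat <- as.matrix(targets)
    if (!all(records$image_id %in% rownames(tmat))) {
      stop("targets do not cover the training manifest")
    }
    tmat <- tmat[records$image_id, , drop = FALSE]
    if (!is.null(colnames(tmat)) && all(classes %in% colnames(tmat))) {
      tmat <- tmat[, classes, drop = FALSE]
    }
  }
  if (ncol(tmat) != spec$n_classes) stop("target width does not match n_classes")

  raw <- lapply(records$path, read_image)
  if (config$augment) {
    # re-augment every epoch: wrap the optimizer loop with fresh features
    impl <- arch_impl(spec)
    params <- impl$init(spec, config$seed)
    state <- list(m = list(), v = list())
    history <- numeric(config$epochs)
    step <- 0L
    decay_map <- as.list(impl$decay)
    with_local_seed(derive_seed(config$seed, 778L), {
      for (ep in seq_len(config$epochs)) {
        x <- featurize_manifest(manifest, spec$input_size,
          mode = "train", images = raw
        )
        perm <- sample.int(nrow(x))
        losses <- c()
        for (start in seq(1L, nrow(x), by = config$batch_size)) {
          rows <- perm[start:min(start + config$batch_size - 1L, nrow(x))]
          fw <- impl$forward(params, x[rows, , drop = FALSE])
          tb <- tmat[rows, , drop = FALSE]
          losses <- c(losses, soft_cross_entropy(fw$log_probs, tb))
          dz <- (exp(fw$log_probs) - tb) / length(rows)
          step <- step + 1L
          upd <- adamw_step(
            params, impl$backward(params, fw$cache, dz),
            state, config, step, decay_map
          )
          params <- upd$params
          state <- upd$state
        }
        history[ep] <- mean(losses)
      }
    })
    fit <- structure(
      list(params = params, spec = spec, history = history, config = config),
      class = "network_fit"
    )
  } else {
    x <- featurize_manifest(manifest, spec$input_size, images = raw)
    fit <- train_network(x, tmat, spec, config)
  }
  structure(
    list(fit = fit, spec = spec, classes = classes, tag = tag),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(
    "trained_model <", x$tag, ">: ", x$spec$architecture, ", ",
    length(x$fit$history), " epochs, final loss ",
    format(utils::tail(x$fit$history, 1), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict per-image class probabilities
#'
#' Deterministic test-mode preprocessing, forward pass, exponentiated
#' log-softmax. Rows sum to 1.
#'
#' @param model a `trained_model`.
#' @param manifest a `cohort_manifest` to score.
#' @return a prediction table: data.frame with `image_id`, `patient_id`,
#'   `model_tag` and one `p_<class>` column per class.
#' @export
predict_image_probabilities <- function(model, manifest) {
  x <- featurize_manifest(manifest, model$spec$input_size)
  probs <- exp(network_log_probs(model$fit, x))
  records <- manifest$records
  out <- data.frame(
    image_id = records$image_id, patient_id = records$patient_id,
    model_tag = model$tag, stringsAsFactors = FALSE
  )
  for (j in seq_along(model$classes)) {
    out[[paste0("p_", model$classes[j])]] <- probs[, j]
  }
  attr(out, "classes") <- model$classes
  out
}
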