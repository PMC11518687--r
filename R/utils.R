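# Internal helpers: deterministic seed streams, rounding, image I/O, audit log.

.sonoclean_env <- new.env(parent = emptyenv())
.sonoclean_env$audit_enabled <- FALSE
.sonoclean_env$audit_stage <- "unstaged"
.sonoclean_env$audit_log <- NULL

#' Round half away from zero
#'
#' Rounding rule used for all count arithmetic in the package (per-class test
#' counts of the stratified split, planted-outlier counts, detector flag
#' counts). Unlike [base::round()], halves always move away from zero, so
#' `round_half_away(0.5) == 1`.
#'
#' @param x numeric vector.
#' @return integer vector of the same length.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.4, -0.5))
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Deterministic 31-bit seed stream derived from a master seed and a stream
# index. Linear congruential mix; stays below 2^31 so set.seed() accepts it.
derive_seed <- function(master, stream) {
  master <- as.double(master %% 2147483647)
  stream <- as.double(stream %% 2147483647)
  as.integer((master * 48271 + stream * 16807 + 12345) %% 2147483647)
}

# Evaluate expr with a local RNG state: seeds, runs, restores global state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Enable or disable the image-access audit
#'
#' When enabled, every image read performed by the package is recorded with
#' the pipeline stage that was active at the time. Used to verify that no
#' training stage ever touches test-split images.
#'
#' @param enabled logical flag.
#' @return invisibly, the previous setting.
#' @export
audit_images <- function(enabled = TRUE) {
  prev <- .sonoclean_env$audit_enabled
  .sonoclean_env$audit_enabled <- isTRUE(enabled)
  if (isTRUE(enabled)) {
    .sonoclean_env$audit_log <- data.frame(
      stage = character(0), path = character(0),
      stringsAsFactors = FALSE
    )
  }
  invisible(prev)
}

#' Retrieve the image-access audit log
#'
#' @return a data.frame with columns `stage` and `path`, one row per image
#'   read since the audit was enabled.
#' @export
audit_log <- function() {
  log <- .sonoclean_env$audit_log
  if (is.null(log)) {
    data.frame(stage = character(0), path = character(0), stringsAsFactors = FALSE)
  } else {
    log
  }
}

# Set the stage label under which subsequent image reads are recorded.
set_audit_stage <- function(stage) {
  prev <- .sonoclean_env$audit_stage
  .sonoclean_env$audit_stage <- stage
  invisible(prev)
}

#' Read a grayscale image as a numeric matrix
#'
#' Decodes a PNG (or any raster `png::readPNG` handles) to a matrix in
#' `[0, 1]`. RGB input is converted to luminance. Reads are recorded in the
#' access audit when it is enabled.
#'
#' @param path file path.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path)
  }
  if (isTRUE(.sonoclean_env$audit_enabled)) {
    .sonoclean_env$audit_log <- rbind(
      .sonoclean_env$audit_log,
      data.frame(
        stage = .sonoclean_env$audit_stage, path = normalizePath(path),
        stringsAsFactors = FALSE
      )
    )
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    # luminance from RGB(A)
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}

# Bilinear resize via EBImage; returns a plain matrix.
resize_matrix <- function(mat, size) {
  if (nrow(mat) == size && ncol(mat) == size) {
    return(mat)
  }
  out <- EBImage::resize(EBImage::Image(mat), w = size, h = size)
  as.matrix(EBImage::imageData(out))
}

clip01 <- function(x) {
  # preserves dim attributes, unlike pmin/pmax with a scalar first argument
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Stable row-wise log-softmax.
log_softmax <- function(z) {
  m <- apply(z, 1L, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

# One-hot matrix from integer class indices (1-based) over K classes.
one_hot <- function(idx, k) {
  n <- length(idx)
  m <- matrix(0, n, k)
  m[cbind(seq_len(n), idx)] <- 1
  m
}
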