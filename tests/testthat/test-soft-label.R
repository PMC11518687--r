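test_that("cluster centroids are class means", {
  x <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
  rownames(x) <- paste0("i", 1:4)
  labels <- c("a", "a", "b", "b")
  model <- fit_cluster_model(x, labels, soft_label_config(reducer = "none"))
  expect_equal(unname(model$centroids), rbind(c(0, 1), c(4, 1)))

  # single sample per class: centroid equals the sample
  m1 <- fit_cluster_model(x[c(1, 3), ], c("a", "b"),
    soft_label_config(reducer = "none")
  )
  expect_equal(unname(m1$centroids), unname(x[c(1, 3), ]))
})

test_that("inverse-distance weights follow the ratio formula", {
  # centroids placed so that distances from the origin are (1, 2, 2)
  model <- structure(
    list(
      centroids = rbind(a = c(1, 0), b = c(0, 2), c = c(-2, 0)),
      center = NULL, rotation = NULL, classes = c("a", "b", "c"),
      epsilon = 1e-9
    ),
    class = "cluster_model"
  )
  w <- inverse_distance_weights(c(0, 0), model)
  expect_equal(as.numeric(w), c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # equidistant point: uniform weights
  weq <- inverse_distance_weights(c(-1 / 3, 2 / 3), model) # not equidistant; use symmetry instead
  model_eq <- model
  model_eq$centroids <- rbind(a = c(1, 0), b = c(-0.5, sqrt(3) / 2), c = c(-0.5, -sqrt(3) / 2))
  weq <- inverse_distance_weights(c(0, 0), model_eq)
  expect_equal(as.numeric(weq), rep(1 / 3, 3), tolerance = 1e-12)

  # at a centroid with epsilon floor: nearly all mass there
  wat <- inverse_distance_weights(c(1, 0), model)
  expect_gt(wat[1, "a"], 0.999)

  # monotone: moving x away from centroid a decreases w_a
  w_far <- inverse_distance_weights(c(-0.5, 0), model)
  expect_lt(w_far[1, "a"], w[1, "a"])
})

test_that("softening reproduces the temperature formula and its limits", {
  w <- matrix(1 / 3, 1, 3, dimnames = list("i1", c("a", "b", "c")))

  # tau = 0: exact one-hot
  s0 <- soften_labels("a", w, tau = 0)
  expect_identical(as.numeric(s0$targets), c(1, 0, 0))

  # uniform weights at tau = 0.7: (1 + 0.7/3)/1.7 and (0.7/3)/1.7
  s7 <- soften_labels("a", w, tau = 0.7)
  expect_equal(as.numeric(s7$targets), c(0.7254902, 0.1372549, 0.1372549),
    tolerance = 1e-7
  )

  # the reference temperature grid is accepted
  for (tau in c(0.6, 0.7, 0.8, 0.9)) {
    expect_s3_class(soften_labels("a", w, tau), "soft_label_matrix")
  }
  expect_error(soften_labels("a", w, tau = -0.1), "tau")
})

test_that("soft targets are row-stochastic with preserved argmax for tau <= 1", {
  set.seed(31)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    n <- sample(1:8, 1)
    w <- matrix(stats::rexp(n * k), n, k)
    w <- w / rowSums(w)
    colnames(w) <- paste0("c", seq_len(k))
    rownames(w) <- paste0("i", seq_len(n))
    hard <- sample(colnames(w), n, replace = TRUE)
    tau <- stats::runif(1, 0, 1)
    s <- soften_labels(hard, w, tau)

    expect_true(all(abs(rowSums(s$targets) - 1) < 1e-9))
    expect_true(all(s$targets >= 0 & s$targets <= 1))
    expect_equal(
      colnames(s$targets)[max.col(s$targets, ties.method = "first")],
      hard
    )
  }
})

test_that("softening is equivariant under class permutation", {
  set.seed(8)
  w <- matrix(stats::rexp(12), 4, 3)
  w <- w / rowSums(w)
  colnames(w) <- c("a", "b", "c")
  rownames(w) <- paste0("i", 1:4)
  hard <- c("a", "c", "b", "a")
  s <- soften_labels(hard, w, 0.7)

  perm <- c(3, 1, 2)
  wp <- w[, perm]
  sp <- soften_labels(hard, wp, 0.7, classes = colnames(wp))
  expect_equal(sp$targets, s$targets[, perm], tolerance = 1e-12)
})

test_that("vectorized weights match a scalar-loop oracle", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    k <- sample(2:5, 1)
    d <- sample(2:6, 1)
    x <- matrix(stats::rnorm(n * d), n, d)
    cen <- matrix(stats::rnorm(k * d), k, d)
    rownames(cen) <- paste0("c", seq_len(k))
    model <- structure(
      list(
        centroids = cen, center = NULL, rotation = NULL,
        classes = rownames(cen), epsilon = 1e-9
      ),
      class = "cluster_model"
    )
    w <- inverse_distance_weights(x, model)
    for (i in seq_len(n)) {
      dists <- vapply(seq_len(k), function(j) {
        sqrt(sum((x[i, ] - cen[j, ])^2))
      }, numeric(1))
      inv <- 1 / pmax(dists, 1e-9)
      expect_equal(as.numeric(w[i, ]), inv / sum(inv), tolerance = 1e-12)
    }
  }
})

test_that("the composed softened set respects contract invariants", {
  out <- tiny_cohort("softset", n_per_class = 5L)
  man <- out$manifest
  fe <- self_feature_extraction(man, make_encoder("pixel", size = 8L))
  for (reducer in c("none", "linear_projection")) {
    res <- build_softened_set(
      man, fe,
      soft_label_config(tau = 0.7, reduce_dim = 4L, reducer = reducer)
    )
    tg <- res$soft_labels$targets
    expect_equal(rownames(tg), man$records$image_id)
    expect_true(all(abs(rowSums(tg) - 1) < 1e-9))
    expect_equal(
      colnames(tg)[max.col(tg, ties.method = "first")],
      man$records$class
    )
  }
})

test_that("softening moves less mass off-target when classes separate more", {
  sep_mass <- vapply(c(0.2, 1.6), function(sep) {
    cfg <- synthetic_config(
      n_patients_per_class = 6L, image_size = 32L,
      separation = sep, seed = 13L
    )
    out <- generate_cohort(cfg, file.path(tempdir(), paste0("softsep_", sep)))
    fe <- self_feature_extraction(
      out$manifest,
      make_encoder("tiny_mlp", size = 16L, dim = 8L, epochs = 40L, seed = 2L)
    )
    res <- build_softened_set(out$manifest, fe, soft_label_config(tau = 0.7))
    tg <- res$soft_labels$targets
    on_target <- tg[cbind(
      seq_len(nrow(tg)),
      match(out$manifest$records$class, colnames(tg))
    )]
    mean(1 - on_target)
  }, numeric(1))
  expect_gt(sep_mass[1], sep_mass[2]) # more overlap, more off-target mass
})

test_that("soft labels survive a CSV round trip", {
  w <- matrix(c(0.5, 0.3, 0.2, 0.1, 0.6, 0.3), 2, 3, byrow = TRUE)
  colnames(w) <- c("a", "b", "c")
  rownames(w) <- c("i1", "i2")
  s <- soften_labels(c("a", "b"), w, 0.7)
  path <- tempfile(fileext = ".csv")
  write_soft_labels(s, path)
  r <- read_soft_labels(path)
  expect_equal(r$targets, s$targets, tolerance = 1e-12)
  expect_equal(r$tau, 0.7)
})
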