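test_that("soft cross-entropy matches closed forms and the scalar oracle", {
  # perfect one-hot prediction: zero loss
  lp <- log(matrix(c(1 - 2e-16, 1e-16, 1e-16), 1, 3))
  expect_equal(soft_cross_entropy(lp, matrix(c(1, 0, 0), 1, 3)), 0, tolerance = 1e-12)

  # uniform prediction: loss = ln K for any stochastic target
  lp_u <- matrix(log(1 / 3), 4, 3)
  tg <- matrix(stats::rexp(12), 4, 3)
  tg <- tg / rowSums(tg)
  expect_equal(soft_cross_entropy(lp_u, tg), log(3), tolerance = 1e-12)

  expect_error(soft_cross_entropy(lp_u, tg[, 1:2]), "shape")
  expect_error(soft_cross_entropy(lp_u, tg * 2), "row-stochastic")

  # scalar double-loop oracle on random instances
  set.seed(17)
  for (rep in 1:10) {
    z <- matrix(stats::rnorm(20 * 4), 20, 4)
    lp <- sonoclean:::log_softmax(z)
    tr <- matrix(stats::rexp(20 * 4), 20, 4)
    tr <- tr / rowSums(tr)
    acc <- 0
    for (i in 1:20) {
      for (c in 1:4) acc <- acc - tr[i, c] * lp[i, c]
    }
    expect_equal(soft_cross_entropy(lp, tr), acc / 20, tolerance = 1e-12)
  }
})

test_that("loss is bounded below by the target entropy", {
  set.seed(23)
  for (rep in 1:20) {
    tg <- matrix(stats::rexp(5 * 3), 5, 3)
    tg <- tg / rowSums(tg)
    lp <- sonoclean:::log_softmax(matrix(stats::rnorm(15), 5, 3))
    entropy <- mean(-rowSums(tg * log(tg)))
    expect_gte(soft_cross_entropy(lp, tg), entropy - 1e-12)
    # equality iff prediction equals target
    expect_equal(soft_cross_entropy(log(tg), tg), entropy, tolerance = 1e-12)
  }
})

test_that("tiny_cnn backward matches numerical gradients", {
  spec <- model_spec("tiny_cnn", 3, input_size = 8L, n_filters = 2L)
  impl <- sonoclean:::cnn_impl()
  set.seed(2)
  x <- matrix(stats::runif(4 * 64), 4, 64)
  tg <- sonoclean:::one_hot(sample(1:3, 4, TRUE), 3)
  params <- impl$init(spec, 1L)
  fw <- impl$forward(params, x)
  gr <- impl$backward(params, fw$cache, (exp(fw$log_probs) - tg) / 4)

  num_grad <- function(nm, i) {
    e <- 1e-6
    p1 <- params
    p1[[nm]][i] <- p1[[nm]][i] + e
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] - e
    (soft_cross_entropy(impl$forward(p1, x)$log_probs, tg) -
      soft_cross_entropy(impl$forward(p2, x)$log_probs, tg)) / (2 * e)
  }
  for (probe in list(c("wc", 5), c("bc", 2), c("w2", 7), c("b2", 1))) {
    expect_equal(
      as.numeric(gr[[probe[1]]])[as.integer(probe[2])],
      num_grad(probe[1], as.integer(probe[2])),
      tolerance = 1e-5, info = probe[1]
    )
  }
})

test_that("training descends and is seed-reproducible", {
  out <- tiny_cohort("train", n_per_class = 5L)
  man <- out$manifest
  spec <- model_spec("tiny_mlp", 3, input_size = 12L)
  cfg <- train_config(epochs = 10L, seed = 4L)

  m1 <- train_classifier(man, NULL, spec, cfg)
  m2 <- train_classifier(man, NULL, spec, cfg)
  expect_length(m1$fit$history, 10L)
  expect_lt(m1$fit$history[10], m1$fit$history[1]) # sanity descent
  expect_identical(m1$fit$history, m2$fit$history)
  expect_identical(m1$fit$params, m2$fit$params)
})

test_that("tau = 0 soft targets reproduce the hard-label trajectory exactly", {
  out <- tiny_cohort("tau0", n_per_class = 5L)
  man <- out$manifest
  onehot <- sonoclean:::one_hot(match(man$records$class, man$classes), 3)
  colnames(onehot) <- man$classes
  rownames(onehot) <- man$records$image_id
  w <- matrix(1 / 3, nrow(onehot), 3, dimnames = dimnames(onehot))
  s0 <- soften_labels(man$records$class, w, tau = 0)

  spec <- model_spec("tiny_mlp", 3, input_size = 12L)
  cfg <- train_config(epochs = 6L, seed = 9L)
  m_hard <- train_classifier(man, NULL, spec, cfg)
  m_soft <- train_classifier(man, s0, spec, cfg)
  expect_identical(m_hard$fit$history, m_soft$fit$history)
})

test_that("a separable cohort is fit to high training accuracy", {
  cfg <- synthetic_config(
    n_patients_per_class = 6L, image_size = 32L,
    separation = 1.6, speckle_sigma = 0.2, seed = 19L
  )
  out <- generate_cohort(cfg, file.path(tempdir(), "separable"))
  man <- out$manifest
  m <- train_classifier(man, NULL, model_spec("tiny_mlp", 3),
    train_config(epochs = 60L, seed = 2L)
  )
  pt <- predict_image_probabilities(m, man)
  pred <- sonoclean:::table_classes(pt)[max.col(sonoclean:::prob_matrix(pt))]
  expect_gte(mean(pred == man$records$class), 0.95)
})

test_that("predicted probability rows are stochastic and deterministic", {
  out <- tiny_cohort("pred", n_per_class = 5L)
  man <- out$manifest
  m <- train_classifier(man, NULL, model_spec("tiny_cnn", 3),
    train_config(epochs = 5L, seed = 3L)
  )
  p1 <- predict_image_probabilities(m, man)
  p2 <- predict_image_probabilities(m, man)
  probs <- sonoclean:::prob_matrix(p1)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_identical(p1, p2)

  # zeroed classifier head gives uniform rows
  m0 <- m
  m0$fit$params$w2[] <- 0
  m0$fit$params$b2[] <- 0
  p0 <- sonoclean:::prob_matrix(predict_image_probabilities(m0, man))
  expect_true(all(abs(p0 - 1 / 3) < 1e-12))
})

test_that("heavy backbone names are pluggable, not silently trained", {
  spec <- model_spec("resnet50", 3)
  out <- tiny_cohort("heavy", n_per_class = 5L)
  expect_error(
    train_classifier(out$manifest, NULL, spec, train_config(epochs = 1L)),
    "register_architecture"
  )
  # registering an implementation makes the same name trainable
  register_architecture("resnet50", sonoclean:::mlp_impl())
  m <- train_classifier(out$manifest, NULL,
    model_spec("resnet50", 3, input_size = 8L),
    train_config(epochs = 1L)
  )
  expect_s3_class(m, "trained_model")
  .sonoclean_env <- asNamespace("sonoclean")$.sonoclean_env
  .sonoclean_env$arch_registry[["resnet50"]] <- NULL
})
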