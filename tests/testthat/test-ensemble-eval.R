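make_table <- function(probs, ids = paste0("i", seq_len(nrow(probs))),
                       patients = ids, tag = "m") {
  out <- data.frame(
    image_id = ids, patient_id = patients, model_tag = tag,
    stringsAsFactors = FALSE
  )
  cls <- paste0("c", seq_len(ncol(probs)))
  for (j in seq_len(ncol(probs))) out[[paste0("p_", cls[j])]] <- probs[, j]
  attr(out, "classes") <- cls
  out
}

test_that("ensembling is a convex combination of member tables", {
  t1 <- make_table(rbind(c(1, 0, 0), c(0.2, 0.5, 0.3)))
  t2 <- make_table(rbind(c(0, 1, 0), c(0.4, 0.4, 0.2)))

  # single member with weight 1 is the identity
  e1 <- ensemble_probabilities(list(t1), ensemble_spec("m", 1))
  expect_equal(sonoclean:::prob_matrix(e1), sonoclean:::prob_matrix(t1))

  # hand-computed equal-weight blend
  e <- ensemble_probabilities(list(t1, t2), ensemble_spec(c("a", "b")))
  expect_equal(unname(sonoclean:::prob_matrix(e)[1, ]), c(0.5, 0.5, 0))

  # member order does not matter under equal weights
  e_rev <- ensemble_probabilities(list(t2, t1), ensemble_spec(c("b", "a")))
  expect_equal(sonoclean:::prob_matrix(e_rev), sonoclean:::prob_matrix(e))

  # convex bounds: output within [min, max] of members per cell
  set.seed(3)
  tabs <- lapply(1:3, function(i) {
    p <- matrix(stats::rexp(15), 5, 3)
    make_table(p / rowSums(p), tag = paste0("m", i))
  })
  w <- c(0.2, 0.5, 0.3)
  eo <- ensemble_probabilities(tabs, ensemble_spec(paste0("m", 1:3), w))
  pm <- lapply(tabs, sonoclean:::prob_matrix)
  lo <- pmin(pm[[1]], pm[[2]], pm[[3]])
  hi <- pmax(pm[[1]], pm[[2]], pm[[3]])
  em <- sonoclean:::prob_matrix(eo)
  expect_true(all(em >= lo - 1e-12 & em <= hi + 1e-12))
  expect_true(all(abs(rowSums(em) - 1) < 1e-9))

  # M identical members equal the single table for any weights
  same <- ensemble_probabilities(list(t1, t1, t1), ensemble_spec(c("a", "b", "c"), c(5, 1, 2)))
  expect_equal(sonoclean:::prob_matrix(same), sonoclean:::prob_matrix(t1))

  expect_error(ensemble_spec(c("a", "b"), c(0, 0)), "positive sum")
  t_bad <- t2[-1, ]
  expect_error(ensemble_probabilities(list(t1, t_bad), ensemble_spec(c("a", "b"))), "image sets")
})

test_that("patient aggregation averages images with a stable tie-break", {
  # single-image patient: row passes through
  t1 <- make_table(rbind(c(0.6, 0.3, 0.1)), patients = "p1")
  a1 <- aggregate_patient(t1)
  expect_equal(unname(as.numeric(a1[1, paste0("p_c", 1:3)])), c(0.6, 0.3, 0.1))

  # two images: mean (0.4, 0.4, 0.2); tie resolved to the lowest class index
  t2 <- make_table(rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3)),
    ids = c("i1", "i2"), patients = c("p1", "p1")
  )
  a2 <- aggregate_patient(t2)
  expect_equal(unname(as.numeric(a2[1, paste0("p_c", 1:3)])), c(0.4, 0.4, 0.2))
  expect_equal(a2$predicted_class, "c1")

  # image order within a patient is irrelevant
  a2r <- aggregate_patient(t2[2:1, ])
  expect_equal(a2r, a2)
})

test_that("patient aggregation commutes with ensembling", {
  set.seed(5)
  pats <- rep(paste0("p", 1:4), each = 3)
  tabs <- lapply(1:2, function(i) {
    p <- matrix(stats::rexp(36), 12, 3)
    make_table(p / rowSums(p), ids = paste0("i", 1:12), patients = pats, tag = paste0("m", i))
  })
  spec <- ensemble_spec(c("m1", "m2"), c(0.3, 0.7))
  agg_then_mix <- 0.3 * as.matrix(aggregate_patient(tabs[[1]])[, paste0("p_c", 1:3)]) +
    0.7 * as.matrix(aggregate_patient(tabs[[2]])[, paste0("p_c", 1:3)])
  mix_then_agg <- as.matrix(
    aggregate_patient(ensemble_probabilities(tabs, spec))[, paste0("p_c", 1:3)]
  )
  expect_equal(mix_then_agg, agg_then_mix, tolerance = 1e-12)
})

# brute-force AUC: mean pairwise comparison with 0.5 tie credit
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

test_that("rank AUC matches the exhaustive pairwise oracle", {
  expect_equal(auc_rank(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  set.seed(41)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties guaranteed
    pos <- stats::runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(scores, pos), auc_oracle(scores, pos), tolerance = 1e-12)
    # antisymmetry under score reversal
    expect_equal(auc_rank(-scores, pos), 1 - auc_rank(scores, pos), tolerance = 1e-12)
  }
})

test_that("ROC points are valid step vertices whose area equals the rank AUC", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    pos <- stats::runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    pts <- roc_points(scores, pos)
    expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(as.numeric(pts[nrow(pts), ]), c(1, 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(sonoclean:::roc_auc(pts), auc_rank(scores, pos), tolerance = 1e-12)
  }

  # perfectly separating scores pass through (0, 1)
  pts <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
})

test_that("metric reports combine the confusion matrix and macro-AUC", {
  probs <- rbind(
    c(0.8, 0.1, 0.1), c(0.7, 0.2, 0.1),
    c(0.1, 0.8, 0.1), c(0.2, 0.7, 0.1),
    c(0.1, 0.1, 0.8), c(0.1, 0.2, 0.7)
  )
  tab <- make_table(probs, patients = paste0("p", 1:6))
  agg <- aggregate_patient(tab)
  truth <- stats::setNames(rep(c("c1", "c2", "c3"), each = 2), paste0("p", 1:6))
  met <- compute_metrics(agg, truth)

  expect_equal(met$accuracy, 1)
  expect_equal(met$macro_auc, 1)
  expect_equal(unname(diag(met$confusion)), c(2L, 2L, 2L))
  expect_equal(sum(met$confusion), met$n_patients)
  expect_true(all(met$per_class$recall == 1))
  expect_true(all(met$per_class$specificity == 1))

  # truth-independent constant probabilities: every one-vs-rest AUC is 0.5
  const <- make_table(matrix(1 / 3, 6, 3), patients = paste0("p", 1:6))
  met_c <- compute_metrics(aggregate_patient(const), truth)
  expect_equal(met_c$macro_auc, 0.5)

  # a class absent from the truth is excluded with a warning
  truth_missing <- stats::setNames(rep(c("c1", "c2"), 3), paste0("p", 1:6))
  expect_warning(
    met_m <- compute_metrics(aggregate_patient(tab), truth_missing),
    "absent"
  )
  expect_true(is.na(met_m$per_class$auc[3]))
})
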