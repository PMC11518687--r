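test_that("out-of-fold extraction covers every image exactly once", {
  out <- tiny_cohort("oof", n_per_class = 5L)
  man <- out$manifest
  fe <- kfold_feature_extraction(man, make_encoder("pixel", size = 8L), k = 5L, seed = 1L)

  expect_setequal(fe$image_ids, man$records$image_id)
  expect_equal(nrow(fe$x), nrow(man$records))
  expect_false(anyNA(fe$x))
  expect_setequal(names(fe$fold_of), man$records$image_id)

  # fold grouping: every image of a patient shares that patient's fold
  by_pat <- tapply(fe$fold_of, man$records$patient_id[match(
    names(fe$fold_of), man$records$image_id
  )], function(f) length(unique(f)))
  expect_true(all(by_pat == 1L))

  # stratification: each class's patients spread over all k folds
  pc <- sonoclean:::patient_classes(man)
  pat_fold <- tapply(fe$fold_of, man$records$patient_id[match(
    names(fe$fold_of), man$records$image_id
  )], unique)
  for (cl in man$classes) {
    folds_cl <- unlist(pat_fold[names(pc)[pc == cl]])
    expect_setequal(unique(folds_cl), 1:5)
  }
})

test_that("identical images in the same fold yield identical feature rows", {
  out <- tiny_cohort("oofdup", n_per_class = 5L)
  man <- out$manifest
  # duplicate one image under a new id for the same patient (same fold)
  rec <- man$records[1, ]
  rec$image_id <- paste0(rec$image_id, "_dup")
  man2 <- sonoclean:::manifest_from_records(rbind(man$records, rec), man$classes)
  fe <- kfold_feature_extraction(man2, make_encoder("pixel", size = 8L), k = 5L, seed = 1L)
  expect_equal(
    fe$x[man$records$image_id[1], ],
    fe$x[rec$image_id, ],
    tolerance = 1e-12
  )
})

test_that("classes smaller than k are rejected", {
  out <- tiny_cohort("oofsmall", n_per_class = 3L)
  expect_error(
    kfold_feature_extraction(out$manifest, make_encoder("pixel"), k = 5L),
    "needs >= k"
  )
})

test_that("merge rules implement the declared set logic", {
  ids <- paste0("i", 1:5)
  m1 <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), ids) # {1,2}
  m2 <- stats::setNames(c(FALSE, TRUE, TRUE, FALSE, FALSE), ids) # {2,3}
  m3 <- stats::setNames(c(FALSE, TRUE, FALSE, FALSE, FALSE), ids) # {2}

  rep_u <- merge_inlier_sets(list(m1, m2, m3), "union")
  expect_equal(rep_u$removed_ids, "i2") # unanimity
  expect_setequal(rep_u$retained_ids, setdiff(ids, "i2"))

  rep_m <- merge_inlier_sets(list(m1, m2, m3), "majority")
  expect_setequal(rep_m$removed_ids, c("i2")) # flagged by > 1.5 detectors

  rep_i <- merge_inlier_sets(list(m1, m2, m3), "intersection")
  expect_setequal(rep_i$removed_ids, c("i1", "i2", "i3"))

  # single mask: removed = its outliers
  expect_equal(merge_inlier_sets(list(m1))$removed_ids, c("i1", "i2"))
  # nothing flagged, nothing removed
  none <- stats::setNames(rep(FALSE, 5), ids)
  expect_length(merge_inlier_sets(list(none, none, none))$removed_ids, 0L)

  expect_error(merge_inlier_sets(list(m1, m2[1:3])), "equal length")
})

test_that("removed fraction never exceeds the smallest detector fraction", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    masks <- lapply(1:3, function(j) stats::runif(n) < stats::runif(1, 0, 0.3))
    rep <- merge_inlier_sets(masks, "union")
    expect_lte(
      length(rep$removed_ids),
      min(vapply(masks, sum, integer(1)))
    )
    expect_setequal(c(rep$removed_ids, rep$retained_ids), as.character(1:n))
  }
})

test_that("zero contamination leaves the training set untouched", {
  out <- tiny_cohort("cleanzero", n_per_class = 5L)
  man <- out$manifest
  fe <- kfold_feature_extraction(man, make_encoder("quality"), k = 5L, seed = 1L)
  cl <- clean_training_set(man, fe, default_detector_configs(0, seed = 1L))
  expect_identical(cl$manifest$records, man$records)
  expect_length(cl$report$removed_ids, 0L)
})

test_that("cleaning never touches patients outside the training manifest", {
  out <- tiny_cohort("cleansplit", n_per_class = 6L)
  man <- out$manifest
  split <- stratified_patient_split(man, 0.3, seed = 3L)
  trm <- split_manifest(man, split, "train")
  tem <- split_manifest(man, split, "test")
  fe <- kfold_feature_extraction(trm, make_encoder("quality"), k = 4L, seed = 1L)
  cl <- clean_training_set(trm, fe, default_detector_configs(0.1, seed = 1L))

  expect_true(all(cl$report$removed_ids %in% trm$records$image_id))
  expect_true(all(cl$report$retained_ids %in% trm$records$image_id))
  expect_length(intersect(cl$manifest$records$image_id, tem$records$image_id), 0L)
  # the union of removed and retained is exactly the training set
  expect_setequal(
    c(cl$report$removed_ids, cl$report$retained_ids),
    trm$records$image_id
  )
})

test_that("whole-set extraction aligns rows with the manifest", {
  out <- tiny_cohort("selffeat", n_per_class = 5L)
  fe <- self_feature_extraction(out$manifest, make_encoder("pixel", size = 8L))
  expect_equal(rownames(fe$x), out$manifest$records$image_id)
  expect_null(fe$fold_of)
})
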