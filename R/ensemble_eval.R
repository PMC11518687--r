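# Probability-weighted model ensembling, patient-level aggregation, and
# case-level evaluation: confusion matrix, accuracy, one-vs-rest macro-AUC
# with 0.5 tie credit, per-class recall/precision/F1/specificity, ROC points.

prob_columns <- function(table) grep("^p_", names(table), value = TRUE)

table_classes <- function(table) {
  cls <- attr(table, "classes")
  if (is.null(cls)) cls <- sub("^p_", "", prob_columns(table))
  cls
}

prob_matrix <- function(table) {
  m <- as.matrix(table[, paste0("p_", table_classes(table)), drop = FALSE])
  rownames(m) <- table$image_id %||% table$patient_id
  m
}

#' Ensemble specification
#'
#' @param members model tags of the ensemble members.
#' @param weights non-negative member weights; normalized to sum to 1
#'   (uniform when `NULL`).
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(members, weights = NULL) {
  if (length(members) < 1L) stop("ensemble needs at least one member")
  if (is.null(weights)) weights <- rep(1, length(members))
  if (length(weights) != length(members)) stop("one weight per member required")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  structure(
    list(members = members, weights = weights / sum(weights)),
    class = "ensemble_spec"
  )
}

#' Named ensemble presets
#'
#' Compositions of the reference backbone families, as they would be
#' combined in a full-scale run; `ensemble2` is the four-member
#' CNN + transformer mixture.
#'
#' @param name preset name.
#' @return an [ensemble_spec()] with uniform weights.
#' @export
ensemble_preset <- function(name = c("ensemble1", "ensemble2", "ensemble3", "ensemble4", "ensemble5")) {
  name <- match.arg(name)
  members <- switch(name,
    ensemble1 = c("densenet169", "densenet201", "vit_b"),
    ensemble2 = c("densenet169", "densenet201", "vit_b", "resnet50"),
    ensemble3 = c("densenet169", "densenet201", "vit_b", "resnet50", "efficientnet_b4"),
    ensemble4 = c("densenet169", "densenet201", "vit_b", "resnet50", "vgg16_bn"),
    ensemble5 = c("densenet169", "densenet201", "vit_b", "resnet50", "efficientnet_b4", "vgg16_bn")
  )
  ensemble_spec(members)
}

#' Weighted ensemble of prediction tables
#'
#' Per image, the output probability row is the weight-normalized convex
#' combination of the member rows, so every output probability lies between
#' the member minimum and maximum and rows still sum to 1.
#'
#' @param tables list of prediction tables over identical image sets (order
#'   may differ), one per member, in `spec$members` order.
#' @param spec an [ensemble_spec()]; uniform over `tables` when `NULL`.
#' @return a prediction table with `model_tag = "ensemble"`.
#' @export
ensemble_probabilities <- function(tables, spec = NULL) {
  if (is.null(spec)) {
    spec <- ensemble_spec(vapply(tables, function(t) t$model_tag[1], character(1)))
  }
  if (length(tables) != length(spec$members)) stop("one table per member required")
  ref <- tables[[1]]
  ids <- ref$image_id
  cls <- table_classes(ref)
  acc <- matrix(0, length(ids), length(cls))
  for (m in seq_along(tables)) {
    tab <- tables[[m]]
    if (!setequal(tab$image_id, ids)) stop("member tables cover different image sets")
    tab <- tab[match(ids, tab$image_id), , drop = FALSE]
    acc <- acc + spec$weights[m] * prob_matrix(tab)
  }
  out <- data.frame(
    image_id = ids, patient_id = ref$patient_id,
    model_tag = "ensemble", stringsAsFactors = FALSE
  )
  for (j in seq_along(cls)) out[[paste0("p_", cls[j])]] <- acc[, j]
  attr(out, "classes") <- cls
  out
}

#' Aggregate image predictions to the patient level
#'
#' The patient (the case) is the smallest evaluation unit: a patient's
#' probability row is the unweighted mean of its image rows, and the
#' predicted class is the argmax with ties broken to the lowest class
#' index.
#'
#' @param table a prediction table.
#' @param classes class order; defaults to the table's.
#' @return data.frame with `patient_id`, `p_<class>` columns and
#'   `predicted_class`.
#' @export
aggregate_patient <- function(table, classes = table_classes(table)) {
  if (any(is.na(table$patient_id))) stop("every image needs a patient_id")
  probs <- as.matrix(table[, paste0("p_", classes), drop = FALSE])
  pids <- sort(unique(table$patient_id))
  agg <- t(vapply(pids, function(p) {
    colMeans(probs[table$patient_id == p, , drop = FALSE])
  }, numeric(length(classes))))
  pred <- classes[max.col(agg, ties.method = "first")]
  out <- data.frame(patient_id = pids, stringsAsFactors = FALSE)
  for (j in seq_along(classes)) out[[paste0("p_", classes[j])]] <- agg[, j]
  out$predicted_class <- pred
  attr(out, "classes") <- classes
  out
}

#' One-vs-rest AUC by pairwise rank comparison
#'
#' Probability of ranking a random positive above a random negative, with
#' tied scores credited 0.5 (midrank / Mann-Whitney formulation).
#'
#' @param scores numeric scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`, or `NA` if either group is empty.
#' @export
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC step-curve vertices for one class
#'
#' Points of the empirical ROC step function, from (0, 0) to (1, 1), one
#' vertex per distinct score threshold (ties produce diagonal segments).
#' The trapezoidal area under the returned points equals [auc_rank()] on
#' the same data.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(positive & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!positive & scores >= t) / n_neg, numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# Trapezoidal area under ROC points.
roc_auc <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
}

#' Patient-level evaluation metrics
#'
#' Confusion matrix (rows = truth, cols = prediction, patient counts),
#' accuracy, macro-AUC (unweighted mean of one-vs-rest [auc_rank()] values),
#' and per-class recall (sensitivity), precision, F1 and specificity. A
#' class absent from the truth gets `NA` AUC and is excluded from the macro
#' mean with a warning.
#'
#' @param patient_probs output of [aggregate_patient()].
#' @param truth named character vector patient_id -> true class (e.g. from
#'   [patient_classes()]).
#' @param classes class order; defaults to the table's.
#' @return an object of class `metrics_report`.
#' @export
compute_metrics <- function(patient_probs, truth, classes = NULL) {
  if (is.null(classes)) classes <- table_classes(patient_probs)
  pids <- patient_probs$patient_id
  if (!all(pids %in% names(truth))) stop("truth missing for some patients")
  y <- factor(truth[pids], levels = classes)
  pred <- factor(patient_probs$predicted_class, levels = classes)
  cm <- table(truth = y, predicted = pred)
  n <- length(pids)
  acc <- sum(diag(cm)) / n

  aucs <- stats::setNames(numeric(length(classes)), classes)
  roc <- list()
  for (cl in classes) {
    pos <- y == cl
    sc <- patient_probs[[paste0("p_", cl)]]
    aucs[cl] <- auc_rank(sc, pos)
    roc[[cl]] <- if (any(pos) && any(!pos)) roc_points(sc, pos) else NULL
  }
  if (anyNA(aucs)) {
    warning(
      "class(es) absent from truth, excluded from macro-AUC: ",
      paste(classes[is.na(aucs)], collapse = ", ")
    )
  }
  macro_auc <- mean(aucs, na.rm = TRUE)

  per_class <- data.frame(
    class = classes,
    recall = NA_real_, precision = NA_real_, f1 = NA_real_,
    specificity = NA_real_, auc = as.numeric(aucs),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per_class$recall[i] <- rec
    per_class$precision[i] <- prec
    per_class$f1[i] <- if (!is.na(rec) && !is.na(prec) && rec + prec > 0) {
      2 * rec * prec / (rec + prec)
    } else {
      NA_real_
    }
    per_class$specificity[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }

  structure(
    list(
      confusion = cm, accuracy = acc, macro_auc = macro_auc,
      per_class = per_class, roc = roc, n_patients = n
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(
    "metrics_report:", x$n_patients, "patients | accuracy",
    format(x$accuracy, digits = 4), "| macro-AUC",
    format(x$macro_auc, digits = 4), "\n"
  )
  print(x$confusion)
  invisible(x)
}

#' Persist a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(
    list(
      accuracy = report$accuracy,
      macro_auc = report$macro_auc,
      n_patients = report$n_patients,
      confusion = as.data.frame.matrix(report$confusion),
      per_class = report$per_class
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read a prediction table as CSV
#'
#' @param table a prediction table.
#' @param path CSV file path.
#' @return `path` invisibly / the table.
#' @export
write_predictions <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(tab, "classes") <- sub("^p_", "", grep("^p_", names(tab), value = TRUE))
  tab
}
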