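# Evaluation: patch -> image aggregation, patient-/image-level accuracy,
# precision/recall/F1 from one-vs-rest confusion counts, confusion matrices
# and ROC/AUC.
#
# The published score definitions are used in their conventional
# orientation correct/total (the printed fractions are inverted and would
# exceed 1): a patient's score is correctly-classified-images / images, the
# patient-level accuracy is the mean score over patients, and image-level
# accuracy is correctly-classified-images / total images. Argmax ties break
# to the lowest class index.

#' Build prediction records
#'
#' @param image_id,patient_id,true_label provenance vectors, one per item.
#' @param probs matrix of class probabilities (rows sum to 1); column names
#'   are the class labels.
#' @param patch_id optional patch identifiers (patch-level records).
#' @return Data frame with provenance columns, one \code{prob.<class>}
#'   column per class, and \code{pred_label} (argmax, ties to the lowest
#'   class index).
#' @export
prediction_records <- function(image_id, patient_id, true_label, probs,
                               patch_id = NULL) {
  stopifnot(is.matrix(probs), !is.null(colnames(probs)))
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probabilities must be nonnegative and sum to 1 per record")
  df <- data.frame(image_id = image_id, patient_id = patient_id,
                   true_label = true_label, stringsAsFactors = FALSE)
  if (!is.null(patch_id)) df <- cbind(data.frame(patch_id = patch_id,
                                                 stringsAsFactors = FALSE), df)
  pm <- as.data.frame(probs)
  names(pm) <- paste0("prob.", colnames(probs))
  df <- cbind(df, pm)
  df$pred_label <- colnames(probs)[max.col(probs, ties.method = "first")]
  df
}

#' Class labels and probability matrix of a record set
#'
#' @param records prediction records.
#' @return \code{record_classes}: character vector of class labels in column
#'   order; \code{record_probs}: the numeric probability matrix.
#' @export
record_classes <- function(records) {
  sub("^prob\\.", "", grep("^prob\\.", names(records), value = TRUE))
}

#' @rdname record_classes
#' @export
record_probs <- function(records) {
  m <- as.matrix(records[, grep("^prob\\.", names(records)), drop = FALSE])
  colnames(m) <- record_classes(records)
  m
}

#' Aggregate patch predictions to image level
#'
#' Per image, the probability vector is the arithmetic mean of its patches'
#' vectors (soft mean, then argmax); provenance and true label are carried
#' through.
#'
#' @param records patch-level prediction records.
#' @return Image-level prediction records (one row per image).
#' @export
aggregate_patch_to_image <- function(records) {
  if (!nrow(records)) stop("aggregation error: no patch records")
  classes <- record_classes(records)
  probs <- record_probs(records)
  ids <- unique(records$image_id)
  agg <- matrix(0, length(ids), length(classes),
                dimnames = list(NULL, classes))
  patient <- character(length(ids))
  truth <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- records$image_id == ids[i]
    agg[i, ] <- colMeans(probs[sel, , drop = FALSE])
    patient[i] <- records$patient_id[sel][1]
    truth[i] <- records$true_label[sel][1]
  }
  prediction_records(image_id = ids, patient_id = patient,
                     true_label = truth, probs = agg)
}

#' Image-level accuracy
#'
#' Correctly classified images over total images.
#'
#' @param records image-level prediction records.
#' @return Fraction in [0, 1].
#' @export
image_level_accuracy <- function(records) {
  if (!nrow(records)) stop("evaluation error: no records")
  mean(records$pred_label == records$true_label)
}

#' Patient-level accuracy
#'
#' Each patient's score is the fraction of their images classified
#' correctly; the global accuracy is the unweighted mean of patient scores.
#'
#' @param records image-level prediction records.
#' @return List with \code{accuracy} and \code{scores} (data frame:
#'   patient_id, n_images, n_correct, score).
#' @export
patient_level_accuracy <- function(records) {
  if (!nrow(records)) stop("evaluation error: no records")
  patients <- unique(records$patient_id)
  scores <- data.frame(patient_id = patients,
                       n_images = NA_integer_, n_correct = NA_integer_,
                       score = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(patients)) {
    sel <- records$patient_id == patients[i]
    scores$n_images[i] <- sum(sel)
    scores$n_correct[i] <- sum(records$pred_label[sel] ==
                               records$true_label[sel])
    scores$score[i] <- scores$n_correct[i] / scores$n_images[i]
  }
  list(accuracy = mean(scores$score), scores = scores)
}

#' One-vs-rest confusion counts
#'
#' @param records prediction records (any level).
#' @param positive_class the class treated as positive.
#' @return List with \code{TP}, \code{FP}, \code{FN}, \code{TN}.
#' @export
confusion_counts <- function(records, positive_class) {
  tp <- sum(records$true_label == positive_class &
            records$pred_label == positive_class)
  fp <- sum(records$true_label != positive_class &
            records$pred_label == positive_class)
  fn <- sum(records$true_label == positive_class &
            records$pred_label != positive_class)
  tn <- sum(records$true_label != positive_class &
            records$pred_label != positive_class)
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean.
#' Zero-denominator cases yield 0 and set the \code{degenerate} attribute
#' with a warning rather than an error.
#'
#' @param counts list with TP, FP, FN (TN unused).
#' @return Named numeric (precision, recall, f1), with attribute
#'   \code{degenerate}.
#' @export
precision_recall_f1 <- function(counts) {
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- div(counts$TP, counts$TP + counts$FP)
  recall <- div(counts$TP, counts$TP + counts$FN)
  f1 <- div(2 * precision * recall, precision + recall)
  if (degenerate)
    warning("degenerate confusion counts: zero denominator, returning 0")
  structure(c(precision = precision, recall = recall, f1 = f1),
            degenerate = degenerate)
}

#' Confusion matrix of prediction records
#'
#' Rows are true classes, columns predicted classes; row sums equal the
#' per-class item counts and the grand total equals the record count.
#'
#' @param records prediction records (patch- or image-level).
#' @return Integer class x class matrix.
#' @export
prediction_confusion <- function(records) {
  classes <- record_classes(records)
  if (!all(records$true_label %in% classes))
    stop("label error: true labels outside the class set")
  m <- unclass(table(factor(records$true_label, classes),
                     factor(records$pred_label, classes)))
  dimnames(m) <- list(classes, classes)
  m
}

#' ROC curve and AUC
#'
#' Thresholds are swept over the unique scores of the positive class; the
#' AUC is computed by the trapezoidal rule over the (FPR, TPR) points. For
#' multiclass records, call once per class (one-vs-rest).
#'
#' @param records prediction records.
#' @param positive_class class whose probability is the score.
#' @return List with \code{points} (data frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
roc_curve_auc <- function(records, positive_class) {
  classes <- record_classes(records)
  if (!positive_class %in% classes)
    stop("label error: unknown positive class ", positive_class)
  score <- records[[paste0("prob.", positive_class)]]
  pos <- records$true_label == positive_class
  if (all(pos) || !any(pos))
    stop("roc error: both classes must be present")
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call_pos <- score >= thr[i]
    tpr[i] <- sum(call_pos & pos) / sum(pos)
    fpr[i] <- sum(call_pos & !pos) / sum(!pos)
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Full metrics report
#'
#' Computes image- and patient-level accuracies (after soft-mean patch
#' aggregation when patch-level records are supplied), per-class and
#' macro-averaged precision/recall/F1, one-vs-rest AUCs and confusion
#' matrices, optionally writing them to disk (metrics JSON, confusion
#' CSVs).
#'
#' @param records patch-level prediction records.
#' @param out_dir optional output directory.
#' @return Metrics list, invisibly when writing.
#' @export
evaluate_predictions <- function(records, out_dir = NULL) {
  image_records <- aggregate_patch_to_image(records)
  classes <- record_classes(records)
  prf <- lapply(classes, function(cl)
    suppressWarnings(precision_recall_f1(confusion_counts(image_records, cl))))
  names(prf) <- classes
  aucs <- vapply(classes, function(cl) {
    ok <- any(image_records$true_label == cl) &&
      !all(image_records$true_label == cl)
    if (ok) roc_curve_auc(image_records, cl)$auc else NA_real_
  }, numeric(1))
  pat <- patient_level_accuracy(image_records)
  metrics <- list(
    patch_accuracy = mean(records$pred_label == records$true_label),
    image_accuracy = image_level_accuracy(image_records),
    patient_accuracy = pat$accuracy,
    per_class = lapply(prf, function(v) as.list(unclass(v))),
    macro_precision = mean(vapply(prf, `[[`, numeric(1), "precision")),
    macro_recall = mean(vapply(prf, `[[`, numeric(1), "recall")),
    macro_f1 = mean(vapply(prf, `[[`, numeric(1), "f1")),
    auc = as.list(aucs),
    n_patches = nrow(records),
    n_images = nrow(image_records),
    n_patients = nrow(pat$scores))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(as.table(prediction_confusion(records))) |>
                       stats::setNames(c("true", "predicted", "count")),
                     file.path(out_dir, "confusion_patch.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(as.table(prediction_confusion(image_records))) |>
                       stats::setNames(c("true", "predicted", "count")),
                     file.path(out_dir, "confusion_image.csv"),
                     row.names = FALSE)
    return(invisible(metrics))
  }
  metrics
}
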