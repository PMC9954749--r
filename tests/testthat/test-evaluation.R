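test_that("patch-to-image aggregation is the soft mean then argmax", {
  probs <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  colnames(probs) <- c("neg", "pos")
  rec <- prediction_records(image_id = c("im1", "im1"),
                            patient_id = c("pA", "pA"),
                            true_label = c("pos", "pos"),
                            probs = probs,
                            patch_id = c("q1", "q2"))
  agg <- aggregate_patch_to_image(rec)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$prob.neg, 0.4)
  expect_equal(agg$prob.pos, 0.6)
  expect_equal(agg$pred_label, "pos")
  # a single-patch image keeps its patch probabilities
  one <- aggregate_patch_to_image(rec[1, ])
  expect_equal(c(one$prob.neg, one$prob.pos), c(0.2, 0.8))
  # aggregated vectors remain on the simplex
  set.seed(2)
  rr <- random_prediction_records(60, k = 4, patch_level = TRUE)
  ag <- aggregate_patch_to_image(rr)
  expect_true(all(abs(rowSums(record_probs(ag)) - 1) < 1e-9))
  expect_error(aggregate_patch_to_image(rr[0, ]), "aggregation")
})

test_that("argmax ties break to the lowest class index", {
  probs <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a", "b")))
  rec <- prediction_records("im1", "p1", "b", probs)
  expect_equal(rec$pred_label, "a")
})

test_that("patient and image accuracies follow correct/total arithmetic", {
  # patient A: 3 of 4 correct; patient B: 1 of 2 correct
  probs <- matrix(0, 6, 2, dimnames = list(NULL, c("x", "y")))
  truth <- c("x", "x", "x", "x", "y", "y")
  pred <- c("x", "x", "x", "y", "y", "x")
  probs[cbind(1:6, match(pred, c("x", "y")))] <- 1
  rec <- prediction_records(paste0("im", 1:6),
                            c(rep("A", 4), rep("B", 2)), truth, probs)
  pat <- patient_level_accuracy(rec)
  expect_equal(sort(pat$scores$score), c(0.5, 0.75))
  expect_equal(pat$accuracy, 0.625)
  expect_equal(image_level_accuracy(rec), 4 / 6)
  # all correct -> 1
  rec_ok <- rec; rec_ok$pred_label <- rec_ok$true_label
  expect_equal(patient_level_accuracy(rec_ok)$accuracy, 1)
  expect_equal(image_level_accuracy(rec_ok), 1)
  expect_error(image_level_accuracy(rec[0, ]), "evaluation")
})

test_that("precision, recall and F1 match hand arithmetic and conventions", {
  prf <- precision_recall_f1(list(TP = 3, FP = 1, FN = 2, TN = 10))
  expect_equal(unname(prf["precision"]), 0.75)
  expect_equal(unname(prf["recall"]), 0.6)
  expect_equal(unname(prf["f1"]), 2 * 0.45 / 1.35)
  expect_false(attr(prf, "degenerate"))
  perfect <- precision_recall_f1(list(TP = 5, FP = 0, FN = 0, TN = 2))
  expect_equal(as.numeric(perfect), c(1, 1, 1))
  expect_warning(zero <- precision_recall_f1(list(TP = 0, FP = 0, FN = 0,
                                                  TN = 4)),
                 "degenerate")
  expect_equal(as.numeric(zero), c(0, 0, 0))
  expect_true(attr(zero, "degenerate"))
})

test_that("metrics agree with brute-force oracles on 100 random sets", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    k <- sample(2:5, 1)
    rec <- random_prediction_records(n, k = k,
                                     n_patients = sample(2:6, 1))
    expect_equal(image_level_accuracy(rec), oracle_image_accuracy(rec))
    expect_equal(patient_level_accuracy(rec)$accuracy,
                 oracle_patient_accuracy(rec))
    cm <- prediction_confusion(rec)
    expect_equal(cm, oracle_confusion(rec, record_classes(rec)))
    expect_equal(sum(cm), nrow(rec))
    expect_equal(unname(rowSums(cm)),
                 unname(as.integer(table(factor(rec$true_label,
                                                record_classes(rec))))))
    # one-vs-rest counts account for every record
    cl <- record_classes(rec)[1]
    cc <- confusion_counts(rec, cl)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, nrow(rec))
  }
})

test_that("AUC equals the rank-statistic identity and its edge cases", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(8:60, 1)
    rec <- random_prediction_records(n, k = 2)
    cl <- record_classes(rec)[2]
    pos <- rec$true_label == cl
    if (!any(pos) || all(pos)) next
    roc <- roc_curve_auc(rec, cl)
    expect_equal(roc$auc, oracle_auc(rec[[paste0("prob.", cl)]], pos),
                 tolerance = 1e-10)
    expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  }
  # perfect separation and constant scores
  probs <- matrix(c(0.9, 0.8, 0.2, 0.1), 4, 1)
  probs <- cbind(probs, 1 - probs)
  colnames(probs) <- c("pos", "neg")
  rec <- prediction_records(paste0("i", 1:4), "p",
                            c("pos", "pos", "neg", "neg"), probs)
  expect_equal(roc_curve_auc(rec, "pos")$auc, 1)
  flat <- prediction_records(paste0("i", 1:4), "p",
                             c("pos", "pos", "neg", "neg"),
                             matrix(0.5, 4, 2,
                                    dimnames = list(NULL, c("pos", "neg"))))
  expect_equal(roc_curve_auc(flat, "pos")$auc, 0.5)
  one_class <- prediction_records(paste0("i", 1:3), "p",
                                  rep("pos", 3),
                                  matrix(0.5, 3, 2,
                                         dimnames = list(NULL,
                                                         c("pos", "neg"))))
  expect_error(roc_curve_auc(one_class, "pos"), "roc error")
})

test_that("patient accuracy is invariant to duplicating a patient's images", {
  set.seed(12)
  rec <- random_prediction_records(12, k = 2, n_patients = 3)
  base <- patient_level_accuracy(rec)$accuracy
  pt <- rec$patient_id[1]
  dup <- rec[rec$patient_id == pt, ]
  dup$image_id <- paste0(dup$image_id, "_copy")
  expect_equal(patient_level_accuracy(rbind(rec, dup))$accuracy, base)
})

test_that("equal images per patient makes the two accuracy levels coincide", {
  set.seed(55)
  for (rep in 1:10) {
    n_pt <- sample(2:5, 1); per <- sample(2:4, 1)
    k <- 3
    probs <- matrix(rexp(n_pt * per * k), n_pt * per, k)
    probs <- probs / rowSums(probs)
    colnames(probs) <- paste0("c", 1:k)
    rec <- prediction_records(
      image_id = paste0("im", seq_len(n_pt * per)),
      patient_id = rep(paste0("pt", seq_len(n_pt)), each = per),
      true_label = sample(paste0("c", 1:k), n_pt * per, replace = TRUE),
      probs = probs)
    expect_equal(patient_level_accuracy(rec)$accuracy,
                 image_level_accuracy(rec), tolerance = 1e-12)
  }
})

test_that("the metrics report writes coherent JSON and CSV artifacts", {
  set.seed(4)
  rec <- random_prediction_records(40, k = 2, patch_level = TRUE)
  out <- tempfile("metrics")
  metrics <- evaluate_predictions(rec, out)
  expect_true(file.exists(file.path(out, "metrics.json")))
  back <- jsonlite::read_json(file.path(out, "metrics.json"),
                              simplifyVector = TRUE)
  expect_equal(back$image_accuracy, metrics$image_accuracy)
  cm <- utils::read.csv(file.path(out, "confusion_image.csv"))
  expect_equal(sum(cm$count), metrics$n_images)
})
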