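# Shared fixtures and independent oracles for the test suite.

# Random H&E-plausible stain matrix. The hematoxylin/eosin ordering
# convention (larger blue OD component) is only meaningful when the two
# vectors differ in blue absorbance, as real H&E dyes do, so the generator
# keeps the blue components well separated.
random_stain_matrix <- function() {
  h <- c(runif(1, 0.4, 0.8), runif(1, 0.5, 0.9), runif(1, 0.3, 0.5))
  e <- c(runif(1, 0.02, 0.15), runif(1, 0.8, 1.0), runif(1, 0.05, 0.15))
  stain_matrix(cbind(h, e))
}

# Tiny two-class cohort on disk; returns list(manifest, dir, plan).
make_tiny_cohort <- function(dir = tempfile("cohort"), seed = 11,
                             patients = 3L, images = 2L, size = 64L,
                             densities = c(6, 50)) {
  cfg <- synthetic_cohort_config(
    list(synthetic_class_spec("benign_like", densities[1],
                              category = "benign"),
         synthetic_class_spec("malignant_like", densities[2],
                              category = "malignant")),
    patients_per_class = patients, images_per_patient = images,
    image_size = size, seed = seed)
  manifest <- generate_cohort(cfg, dir)
  list(manifest = manifest, dir = dir)
}

# Random prediction records over n items, k classes, p patients.
random_prediction_records <- function(n, k = 3L, n_patients = 4L,
                                      patch_level = FALSE) {
  classes <- paste0("cls", seq_len(k))
  raw <- matrix(rexp(n * k), n, k)
  probs <- raw / rowSums(raw)
  colnames(probs) <- classes
  image_id <- if (patch_level) paste0("img", sample.int(max(2, n %/% 3), n,
                                                        replace = TRUE))
              else paste0("img", seq_len(n))
  patients <- paste0("pt", seq_len(n_patients))
  pt_of_img <- stats::setNames(sample(patients, length(unique(image_id)),
                                      replace = TRUE), unique(image_id))
  lbl_of_img <- stats::setNames(sample(classes, length(unique(image_id)),
                                       replace = TRUE), unique(image_id))
  prediction_records(
    image_id = image_id,
    patient_id = unname(pt_of_img[image_id]),
    true_label = unname(lbl_of_img[image_id]),
    probs = probs,
    patch_id = if (patch_level) paste0("patch", seq_len(n)) else NULL)
}

# --- brute-force oracles (kept deliberately naive) ---

oracle_patch_budget <- function(class_counts, beta) {
  out <- integer(length(class_counts))
  total <- 0
  for (x in class_counts) total <- total + x
  mean_x <- total / length(class_counts)
  for (i in seq_along(class_counts))
    out[i] <- as.integer(ceiling(mean_x / class_counts[i] * beta))
  names(out) <- names(class_counts)
  out
}

oracle_image_accuracy <- function(records) {
  good <- 0
  for (i in seq_len(nrow(records)))
    if (records$pred_label[i] == records$true_label[i]) good <- good + 1
  good / nrow(records)
}

oracle_patient_accuracy <- function(records) {
  scores <- c()
  for (pt in unique(records$patient_id)) {
    rows <- records[records$patient_id == pt, ]
    scores <- c(scores, mean(rows$pred_label == rows$true_label))
  }
  mean(scores)
}

oracle_confusion <- function(records, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_len(nrow(records)))
    m[records$true_label[i], records$pred_label[i]] <-
      m[records$true_label[i], records$pred_label[i]] + 1L
  m
}

# AUC as the normalized Mann-Whitney U statistic (rank identity).
oracle_auc <- function(score, is_pos) {
  r <- rank(score)
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
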