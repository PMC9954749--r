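# Cohort manifests, directory-tree ingestion, and patient-aware splitting.
#
# Two dataset layouts are supported:
#   * BreakHis-style: root/category/subclass/patient/magnification/img.png,
#     with category in {benign, malignant};
#   * class-folder style (NCT-CRC-like): root/class/img.png, no patient
#     structure (each image becomes its own pseudo-patient, so image-level
#     and patient-level metrics coincide there).
# The native BreakHis filename encoding is deliberately not parsed: the
# documented directory layout plus a CSV manifest is the ingestion contract.
# Users holding the real download can create the layout with one rename pass
# (category/subclass from the directory names, patient from the slide id,
# magnification from the leaf folders).

.breakhis_subclasses <- list(
  benign = c("ADE", "FID", "PHT", "TUA"),
  malignant = c("PAC", "DUC", "LOC", "MUC"))

.crc_classes <- c("ADI", "BACK", "DEB", "LYM", "MUC", "MUS", "NORM",
                  "STR", "TUM")

.magnifications <- c("40X", "100X", "200X", "400X", "none")

.image_ext <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Scan a BreakHis-style directory tree
#'
#' Expects \code{root/category/subclass/patient/magnification/image.png}
#' with categories \code{benign}/\code{malignant} and the eight breast
#' subtype codes (ADE, FID, PHT, TUA; PAC, DUC, LOC, MUC). Non-image files
#' are ignored; ordering is lexicographic and deterministic.
#'
#' @param root tree root.
#' @param strict enforce the eight breast-subtype codes; with
#'   \code{strict = FALSE} any subclass directory name is accepted (useful
#'   for synthetic cohorts that mimic the layout).
#' @return Sample manifest: data frame with columns \code{image_id},
#'   \code{path}, \code{patient_id}, \code{category}, \code{subclass},
#'   \code{magnification}.
#' @export
scan_breakhis_tree <- function(root, strict = TRUE) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  files <- files[tolower(tools::file_ext(files)) %in% .image_ext]
  if (!length(files)) {
    warning("empty tree: no image files under ", root)
    return(empty_manifest())
  }
  parts <- strsplit(files, "/", fixed = TRUE)
  bad <- lengths(parts) != 5
  if (any(bad))
    stop("unexpected layout (want category/subclass/patient/magnification/",
         "image): ", files[which(bad)[1]])
  m <- do.call(rbind, parts)
  if (!all(m[, 1] %in% names(.breakhis_subclasses)))
    stop("taxonomy: unknown category directory ",
         setdiff(m[, 1], names(.breakhis_subclasses))[1])
  if (strict) {
    ok <- vapply(seq_len(nrow(m)), function(i)
      m[i, 2] %in% .breakhis_subclasses[[m[i, 1]]], logical(1))
    if (!all(ok))
      stop("taxonomy: subclass ", m[!ok, 2][1], " not valid under category ",
           m[!ok, 1][1])
  }
  if (!all(m[, 4] %in% .magnifications))
    stop("taxonomy: unknown magnification directory ",
         setdiff(m[, 4], .magnifications)[1])
  data.frame(
    image_id = paste(m[, 3], m[, 4],
                     tools::file_path_sans_ext(m[, 5]), sep = "_"),
    path = file.path(root, files),
    patient_id = m[, 3],
    category = m[, 1],
    subclass = m[, 2],
    magnification = m[, 4],
    stringsAsFactors = FALSE)
}

#' Scan a class-folder directory tree
#'
#' Expects \code{root/class/image.png}. In strict mode the class folders
#' must be the nine colorectal tissue codes (ADI, BACK, DEB, LYM, MUC, MUS,
#' NORM, STR, TUM); permissive mode accepts arbitrary folder names. Each
#' image becomes its own pseudo-patient.
#'
#' @param root tree root.
#' @param strict enforce the nine-class taxonomy.
#' @return Sample manifest (see \code{\link{scan_breakhis_tree}});
#'   \code{category} and \code{magnification} are \code{"none"}.
#' @export
scan_class_folder_tree <- function(root, strict = TRUE) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  files <- files[tolower(tools::file_ext(files)) %in% .image_ext]
  if (!length(files)) {
    warning("empty tree: no image files under ", root)
    return(empty_manifest())
  }
  parts <- strsplit(files, "/", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("unexpected layout (want class/image): ",
         files[which(lengths(parts) != 2)[1]])
  m <- do.call(rbind, parts)
  if (strict && !all(m[, 1] %in% .crc_classes))
    stop("taxonomy: unknown class folder ",
         setdiff(m[, 1], .crc_classes)[1],
         " (use strict = FALSE for arbitrary class names)")
  ids <- paste(m[, 1], tools::file_path_sans_ext(m[, 2]), sep = "_")
  data.frame(
    image_id = ids,
    path = file.path(root, files),
    patient_id = ids,               # pseudo-patient: one per image
    category = "none",
    subclass = m[, 1],
    magnification = "none",
    stringsAsFactors = FALSE)
}

empty_manifest <- function() {
  data.frame(image_id = character(), path = character(),
             patient_id = character(), category = character(),
             subclass = character(), magnification = character(),
             stringsAsFactors = FALSE)
}

#' Read and write sample manifests
#'
#' CSV with columns image_id, path, patient_id, category, subclass,
#' magnification; the round trip reproduces the manifest exactly.
#'
#' @param manifest sample manifest data frame.
#' @param path CSV file path.
#' @return \code{read_manifest}: the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
}

# round-half-up (R's round() is round-half-even)
.round_half_up <- function(x) floor(x + 0.5)

#' Patient-level train/test split
#'
#' Shuffles the distinct patients with the given seed and cuts at
#' \code{round(ratio * n_patients)} (half-up). No image of a test patient
#' can appear in training, preventing patient leakage by construction.
#'
#' @param manifest sample manifest.
#' @param ratio training fraction (default 0.70).
#' @param seed integer seed.
#' @return An object of class \code{"split_plan"}: list with
#'   \code{train_patients}, \code{test_patients}, \code{ratio}, \code{seed}.
#' @export
make_patient_split <- function(manifest, ratio = 0.7, seed = 1L) {
  patients <- sort(unique(manifest$patient_id))
  if (length(patients) < 2)
    stop("split: need at least 2 patients, found ", length(patients))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  shuffled <- .with_seed(seed, sample(patients))
  n_train <- .round_half_up(ratio * length(patients))
  n_train <- min(max(n_train, 1L), length(patients) - 1L)
  structure(list(train_patients = sort(shuffled[seq_len(n_train)]),
                 test_patients = sort(shuffled[-seq_len(n_train)]),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Patient split (ratio ", x$ratio, ", seed ", x$seed, "): ",
      length(x$train_patients), " train / ",
      length(x$test_patients), " test patients\n", sep = "")
  invisible(x)
}

#' Apply a split plan to a manifest
#'
#' @param manifest sample or patch manifest with a \code{patient_id} column.
#' @param plan a \code{\link{make_patient_split}} plan.
#' @param side \code{"train"} or \code{"test"}.
#' @return The manifest rows belonging to that side.
#' @export
split_side <- function(manifest, plan, side = c("train", "test")) {
  side <- match.arg(side)
  keep <- if (side == "train") plan$train_patients else plan$test_patients
  manifest[manifest$patient_id %in% keep, , drop = FALSE]
}

#' Patient-stratified cross-validation folds
#'
#' Patients are shuffled with the seed and dealt round-robin into \code{k}
#' folds, so fold sizes differ by at most one and folds partition the
#' patient set.
#'
#' @param manifest sample manifest.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class \code{"cv_folds"}: list with \code{k},
#'   \code{assignment} (named integer vector patient -> fold), \code{seed}.
#' @export
make_cv_folds <- function(manifest, k = 5L, seed = 1L) {
  patients <- sort(unique(manifest$patient_id))
  if (length(patients) < k)
    stop("folds: need at least k = ", k, " patients, found ",
         length(patients))
  shuffled <- .with_seed(seed, sample(patients))
  assignment <- rep(seq_len(k), length.out = length(shuffled))
  names(assignment) <- shuffled
  assignment <- assignment[order(names(assignment))]
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "cv_folds")
}

#' @export
print.cv_folds <- function(x, ...) {
  cat("Patient-level CV (k = ", x$k, ", seed ", x$seed, "); fold sizes: ",
      paste(tabulate(x$assignment, x$k), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Serialize split plans and CV folds to JSON
#'
#' @param x a \code{"split_plan"} or \code{"cv_folds"} object.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_split <- function(x, path) {
  if (inherits(x, "split_plan")) {
    jsonlite::write_json(list(kind = "split_plan",
                              train_patients = x$train_patients,
                              test_patients = x$test_patients,
                              ratio = x$ratio, seed = x$seed),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "cv_folds")) {
    jsonlite::write_json(list(kind = "cv_folds", k = x$k,
                              patients = names(x$assignment),
                              fold = unname(x$assignment), seed = x$seed),
                         path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported object")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$kind, "split_plan")) {
    structure(list(train_patients = doc$train_patients,
                   test_patients = doc$test_patients,
                   ratio = doc$ratio, seed = doc$seed),
              class = "split_plan")
  } else if (identical(doc$kind, "cv_folds")) {
    assignment <- as.integer(doc$fold)
    names(assignment) <- doc$patients
    structure(list(k = as.integer(doc$k), assignment = assignment,
                   seed = doc$seed),
              class = "cv_folds")
  } else stop("unrecognized split document")
}

#' The published BreakHis census table
#'
#' Per-subclass image counts at the four magnifications together with
#' per-subclass patient counts, as shipped in
#' \code{inst/extdata/breakhis_table2.csv}.
#'
#' @return Data frame with columns \code{category}, \code{subclass},
#'   \code{m40}, \code{m100}, \code{m200}, \code{m400}, \code{sum},
#'   \code{patients}.
#' @export
breakhis_census_table <- function() {
  path <- system.file("extdata", "breakhis_table2.csv", package = "fabnet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Census totals of a cohort table
#'
#' Checks the arithmetic of a per-subclass census: recomputes each row's sum
#' over magnifications and the grand totals.
#'
#' @param census data frame as returned by
#'   \code{\link{breakhis_census_table}}.
#' @return List with \code{total_images}, \code{total_patients},
#'   \code{per_subclass} (named row sums over the magnification columns).
#' @export
census_totals <- function(census) {
  mags <- c("m40", "m100", "m200", "m400")
  per <- rowSums(census[, mags])
  names(per) <- census$subclass
  list(total_images = sum(per),
       total_patients = sum(census$patients),
       per_subclass = per)
}
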