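test_that("BreakHis-style trees scan to one deterministic record per image", {
  root <- tempfile("tree")
  for (pt in c("ptA", "ptB", "ptC"))
    for (mag in c("40X", "100X"))
      for (i in 1:4) {
        d <- file.path(root, "benign", "PHT", pt, mag)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        png::writePNG(array(runif(12), c(2, 2, 3)),
                      file.path(d, sprintf("img%d.png", i)))
      }
  records <- scan_breakhis_tree(root)
  expect_equal(nrow(records), 3 * 2 * 4)
  expect_true(all(records$category == "benign" & records$subclass == "PHT"))
  expect_identical(records, scan_breakhis_tree(root))   # deterministic
  # non-image files are ignored
  writeLines("x", file.path(root, "benign", "PHT", "ptA", "40X", "notes.txt"))
  expect_equal(nrow(scan_breakhis_tree(root)), 24)
  # unknown subclass directory is a taxonomy error
  d <- file.path(root, "benign", "WRONG", "ptA", "40X")
  dir.create(d, recursive = TRUE)
  png::writePNG(array(0.5, c(2, 2, 3)), file.path(d, "img1.png"))
  expect_error(scan_breakhis_tree(root), "taxonomy")
})

test_that("class-folder trees scan with pseudo-patients and strict taxonomy", {
  root <- tempfile("crc")
  for (cls in c("ADI", "TUM", "STR"))
    for (i in 1:5) {
      dir.create(file.path(root, cls), recursive = TRUE,
                 showWarnings = FALSE)
      png::writePNG(array(runif(12), c(2, 2, 3)),
                    file.path(root, cls, sprintf("im%d.png", i)))
    }
  records <- scan_class_folder_tree(root)
  expect_equal(nrow(records), 15)
  expect_identical(records$patient_id, records$image_id)
  expect_true(all(records$category == "none"))
  dir.create(file.path(root, "mystery"))
  png::writePNG(array(0.5, c(2, 2, 3)), file.path(root, "mystery", "a.png"))
  expect_error(scan_class_folder_tree(root), "taxonomy")
  perm <- scan_class_folder_tree(root, strict = FALSE)
  expect_true("mystery" %in% perm$subclass)
})

test_that("generated cohorts scan back to their manifests exactly", {
  co <- make_tiny_cohort(patients = 2, images = 2, size = 32)
  scanned <- scan_breakhis_tree(co$dir, strict = FALSE)
  m <- co$manifest[order(co$manifest$image_id), ]
  s <- scanned[order(scanned$image_id), ]
  rownames(m) <- rownames(s) <- NULL
  expect_equal(s[, c("image_id", "patient_id", "category", "subclass",
                     "magnification")],
               m[, c("image_id", "patient_id", "category", "subclass",
                     "magnification")])
})

test_that("manifests round-trip through CSV", {
  co <- make_tiny_cohort(patients = 2, images = 1, size = 32)
  path <- tempfile(fileext = ".csv")
  write_manifest(co$manifest, path)
  back <- read_manifest(path)
  rownames(back) <- rownames(co$manifest) <- NULL
  expect_equal(back, co$manifest)
})

test_that("patient splits are exact, disjoint and seeded", {
  manifest <- data.frame(image_id = paste0("i", 1:40),
                         path = "x", patient_id = rep(paste0("pt", 1:10), 4),
                         category = "none", subclass = "a",
                         magnification = "none")
  plan <- make_patient_split(manifest, ratio = 0.7, seed = 4)
  expect_length(plan$train_patients, 7)
  expect_length(plan$test_patients, 3)
  expect_length(intersect(plan$train_patients, plan$test_patients), 0)
  expect_setequal(c(plan$train_patients, plan$test_patients),
                  unique(manifest$patient_id))
  expect_identical(plan, make_patient_split(manifest, 0.7, seed = 4))
  # image sets of the two sides are disjoint
  tr <- split_side(manifest, plan, "train")
  te <- split_side(manifest, plan, "test")
  expect_length(intersect(tr$image_id, te$image_id), 0)
  expect_equal(nrow(tr) + nrow(te), nrow(manifest))
  expect_error(make_patient_split(manifest[manifest$patient_id == "pt1", ]),
               "split")
})

test_that("cross-validation folds partition patients with near-equal sizes", {
  mk <- function(n) data.frame(image_id = paste0("i", seq_len(n)), path = "x",
                               patient_id = paste0("pt", seq_len(n)),
                               category = "none", subclass = "a",
                               magnification = "none")
  f10 <- make_cv_folds(mk(10), k = 5, seed = 1)
  expect_equal(unname(tabulate(f10$assignment, 5)), rep(2L, 5))
  f11 <- make_cv_folds(mk(11), k = 5, seed = 1)
  expect_setequal(tabulate(f11$assignment, 5), c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(names(f11$assignment), mk(11)$patient_id)
  expect_error(make_cv_folds(mk(4), k = 5), "folds")
})

test_that("no patient ever straddles a split or fold on random cohorts", {
  set.seed(8)
  for (rep in 1:20) {
    n_pt <- sample(5:30, 1)
    manifest <- data.frame(
      image_id = paste0("i", 1:(n_pt * 3)), path = "x",
      patient_id = sample(rep(paste0("pt", 1:n_pt), 3)),
      category = "none", subclass = "a", magnification = "none")
    plan <- make_patient_split(manifest, 0.7, seed = rep)
    tr <- split_side(manifest, plan, "train")
    te <- split_side(manifest, plan, "test")
    expect_length(intersect(tr$patient_id, te$patient_id), 0)
    folds <- make_cv_folds(manifest, k = 5, seed = rep)
    expect_length(folds$assignment, n_pt)
    expect_lte(diff(range(tabulate(folds$assignment, 5))), 1)
  }
})

test_that("split plans and folds serialize to JSON and back", {
  manifest <- data.frame(image_id = paste0("i", 1:12), path = "x",
                         patient_id = paste0("pt", rep(1:6, 2)),
                         category = "none", subclass = "a",
                         magnification = "none")
  plan <- make_patient_split(manifest, 0.7, seed = 3)
  p1 <- tempfile(fileext = ".json")
  write_split(plan, p1)
  back <- read_split(p1)
  expect_equal(back$train_patients, plan$train_patients)
  expect_equal(back$test_patients, plan$test_patients)
  folds <- make_cv_folds(manifest, k = 3, seed = 3)
  p2 <- tempfile(fileext = ".json")
  write_split(folds, p2)
  fback <- read_split(p2)
  expect_equal(fback$assignment, folds$assignment)
})

test_that("the published census arithmetic checks out", {
  census <- breakhis_census_table()
  totals <- census_totals(census)
  expect_equal(totals$total_images, 7909)
  expect_equal(totals$total_patients, 82)
  expect_equal(unname(totals$per_subclass["PHT"]), 569)
  # every row's printed sum equals the recomputed magnification sum
  expect_equal(unname(totals$per_subclass), census$sum)
})
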