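test_that("optical-density transform round-trips and matches direct values", {
  set.seed(1)
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  expect_lte(max(abs(od_to_rgb(rgb_to_od(img)) - img)), 1)
  # I = 254 is the white point of the +1 guard
  expect_equal(rgb_to_od(array(254, c(2, 2, 3))),
               array(0, c(2, 2, 3)))
  # I = 24 -> -log10(25/255)
  expect_equal(rgb_to_od(array(24, c(1, 1, 3)))[1, 1, 1],
               -log10(25 / 255), tolerance = 1e-12)
  expect_equal(-log10(25 / 255), 1.0086, tolerance = 1e-4)
  expect_error(rgb_to_od(array(-3, c(2, 2, 3))), "0, 255")
})

test_that("ground-truth stain vectors are recovered from synthetic renders", {
  set.seed(99)
  errs <- replicate(20, {
    sm <- random_stain_matrix()
    gen <- generate_tissue_image(
      synthetic_class_spec("t", nucleus_density = 20), sm,
      size = 96, seed = sample.int(1e6, 1))
    est <- estimate_stain_matrix(gen$image)
    max(stain_angle_deg(est[, 1], unclass(sm)[, 1]),
        stain_angle_deg(est[, 2], unclass(sm)[, 2]))
  })
  expect_lt(median(errs), 2)
  # the default reference basis is recovered within 2 degrees per vector
  ref <- default_stain_reference()$stains
  gen <- generate_tissue_image(synthetic_class_spec("t", 25), ref,
                               size = 96, seed = 7)
  est <- estimate_stain_matrix(gen$image)
  expect_lt(stain_angle_deg(est[, 1], unclass(ref)[, 1]), 2)
  expect_lt(stain_angle_deg(est[, 2], unclass(ref)[, 2]), 2)
})

test_that("background and single-stain images raise the documented errors", {
  expect_error(estimate_stain_matrix(array(255, c(64, 64, 3))), "no-tissue")
  pure_eosin <- generate_tissue_image(
    synthetic_class_spec("bg", nucleus_density = 0), size = 96, seed = 5)
  expect_error(estimate_stain_matrix(pure_eosin$image), "degenerate-stain")
  expect_error(normalize_image(array(255, c(64, 64, 3))), "no-tissue")
})

test_that("concentrations solve the least-squares decomposition", {
  ref <- default_stain_reference()$stains
  S <- unclass(ref)
  od <- array(0, c(2, 2, 3))
  od[1, 1, ] <- S[, 1]          # pure hematoxylin, concentration 1
  od[1, 2, ] <- 2 * S[, 2]      # pure eosin, concentration 2
  cc <- compute_concentrations(od, ref)
  expect_equal(cc[1, 1, ], c(1, 0), tolerance = 1e-10)
  expect_equal(cc[1, 2, ], c(0, 2), tolerance = 1e-10)
  expect_equal(cc[2, 2, ], c(0, 0))

  # least-squares optimality: residual no worse than any basis-grid solution
  set.seed(3)
  od_px <- runif(3, 0.2, 1)
  odm <- array(od_px, c(1, 1, 3))
  c_fit <- compute_concentrations(odm, ref)[1, 1, ]
  res_fit <- sqrt(sum((od_px - S %*% c_fit)^2))
  grid <- as.matrix(expand.grid(seq(0, 2, by = 0.01), seq(0, 2, by = 0.01)))
  res_grid <- min(sqrt(colSums((od_px - S %*% t(grid))^2)))
  expect_lte(res_fit, res_grid + 1e-9)
})

test_that("normalization is a fixed point on reference-rendered images and idempotent", {
  ref <- default_stain_reference()
  gen <- generate_tissue_image(synthetic_class_spec("t", 25), ref$stains,
                               size = 96, seed = 13)
  # scale target taken from the true concentration field of this render
  q99 <- apply(matrix(gen$truth$concentrations, ncol = 2), 2,
               quantile, probs = 0.99)
  out <- normalize_image(gen$image, reference = ref$stains,
                         reference_max_c = q99)
  expect_lte(max(abs(out - gen$image)), 2)

  # idempotence under the default reference: within +/-2 intensity apart
  # from the <0.1% of near-black pixels whose concentrations are destroyed
  # by 8-bit clipping (overlapping nuclei)
  n1 <- normalize_image(gen$image)
  n2 <- normalize_image(n1)
  d <- abs(n2 - n1)
  expect_lte(quantile(d, 0.999), 2)
  expect_lte(max(d), 5)
  expect_true(all(n1 >= 0 & n1 <= 255))
})

test_that("normalization collapses stain variation between sources", {
  # same concentration field rendered through two different stain bases
  cs <- synthetic_class_spec("t", 25)
  set.seed(21)
  smA <- random_stain_matrix()
  smB <- random_stain_matrix()
  genA <- generate_tissue_image(cs, smA, size = 96, seed = 31)
  conc <- genA$truth$concentrations
  render <- function(sm) {
    od <- matrix(conc, ncol = 2) %*% t(unclass(sm))
    img <- round(255 * 10^(-od))
    img[img > 255] <- 255
    array(pmax(img, 0), dim(genA$image))
  }
  outA <- normalize_image(render(smA))
  outB <- normalize_image(render(smB))
  expect_lte(mean(abs(outA - outB)), 2)
  expect_lte(stats::quantile(abs(outA - outB), 0.99), 6)
})

test_that("stain matrix serializes to a JSON document and back", {
  sm <- default_stain_reference()$stains
  path <- tempfile(fileext = ".json")
  write_stain_matrix(sm, path)
  back <- read_stain_matrix(path)
  expect_equal(unclass(back), unclass(sm), tolerance = 1e-12)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(unlist(doc), 6)
})
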