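# Seeded synthetic H&E-like image generation. Images are rendered through
# the Beer-Lambert law: a per-pixel two-stain concentration field (nuclei
# carry hematoxylin, the background carries eosin) is mixed through a known
# stain matrix, I = 255 * 10^(-S %*% c). Because the ground-truth stains and
# concentrations are returned, stain-matrix recovery and normalization
# fixed-point properties can be tested exactly, and class-dependent nuclear
# density makes cohorts separable for end-to-end training tests.

#' Synthetic tissue class specification
#'
#' @param name class label (used as subclass in manifests).
#' @param nucleus_density expected nuclei per 100x100 pixels.
#' @param radius_range min/max nucleus semi-axis in pixels.
#' @param eosin_level background eosin concentration (OD units). The default
#'   0.4 keeps background pixels above the usual 0.15 OD tissue threshold so
#'   the eosin direction is observable.
#' @param category benign/malignant tag used for BreakHis-style trees.
#' @return An object of class \code{"synthetic_class_spec"}.
#' @export
synthetic_class_spec <- function(name, nucleus_density,
                                 radius_range = c(3, 6),
                                 eosin_level = 0.4,
                                 category = "benign") {
  stopifnot(nucleus_density >= 0, length(radius_range) == 2,
            all(radius_range > 0), radius_range[1] <= radius_range[2],
            eosin_level >= 0)
  structure(list(name = name, nucleus_density = nucleus_density,
                 radius_range = radius_range, eosin_level = eosin_level,
                 category = category),
            class = "synthetic_class_spec")
}

# nucleus scale factor per emulated magnification
.mag_scale <- c("40X" = 0.5, "100X" = 1, "200X" = 1.5, "400X" = 2,
                "none" = 1)

#' Generate one synthetic H&E tissue image
#'
#' Draws a Poisson number of elliptical nuclei (expected
#' \code{nucleus_density} per 100x100 px), fills a hematoxylin concentration
#' field inside them and an eosin field outside (nuclei displace cytoplasm),
#' applies mild per-pixel concentration jitter, and renders through the
#' given stain matrix. Deterministic at byte level for a fixed seed.
#'
#' @param class_spec a \code{\link{synthetic_class_spec}}.
#' @param stains ground-truth \code{\link{stain_matrix}}; defaults to
#'   \code{\link{default_stain_reference}}.
#' @param size image side in pixels (square).
#' @param seed integer seed.
#' @param magnification one of 40X/100X/200X/400X/none; scales nucleus size.
#' @return List with \code{image} (8-bit RGB array), \code{truth} (list:
#'   \code{nucleus_count}, \code{concentrations} (size x size x 2 array),
#'   \code{stains}).
#' @export
generate_tissue_image <- function(class_spec, stains = NULL, size = 96L,
                                  seed = 1L, magnification = "none") {
  stopifnot(inherits(class_spec, "synthetic_class_spec"))
  if (is.null(stains)) stains <- default_stain_reference()$stains
  stopifnot(inherits(stains, "stain_matrix"))
  scale <- .mag_scale[[match.arg(magnification, names(.mag_scale))]]
  size <- as.integer(size)
  .with_seed(seed, {
    lambda <- class_spec$nucleus_density * (size / 100)^2
    n_nuc <- stats::rpois(1, lambda)
    ch <- matrix(0, size, size)          # hematoxylin concentration
    if (n_nuc > 0) {
      cx <- stats::runif(n_nuc, 1, size)
      cy <- stats::runif(n_nuc, 1, size)
      r1 <- stats::runif(n_nuc, class_spec$radius_range[1],
                         class_spec$radius_range[2]) * scale
      r2 <- stats::runif(n_nuc, class_spec$radius_range[1],
                         class_spec$radius_range[2]) * scale
      th <- stats::runif(n_nuc, 0, pi)
      amp <- stats::runif(n_nuc, 0.8, 1.2)
      xs <- matrix(rep(seq_len(size), each = size), size)   # column coord
      ys <- matrix(rep(seq_len(size), size), size)          # row coord
      for (i in seq_len(n_nuc)) {
        dx <- xs - cx[i]; dy <- ys - cy[i]
        u <- dx * cos(th[i]) + dy * sin(th[i])
        v <- -dx * sin(th[i]) + dy * cos(th[i])
        inside <- (u / r1[i])^2 + (v / r2[i])^2 <= 1
        ch[inside] <- ch[inside] + amp[i]
      }
    }
    nucleus_mask <- ch > 0
    ce <- matrix(class_spec$eosin_level, size, size)
    ce[nucleus_mask] <- 0                # nuclei displace cytoplasm
    jitter_h <- matrix(stats::runif(size^2, 0.9, 1.1), size)
    jitter_e <- matrix(stats::runif(size^2, 0.9, 1.1), size)
    conc <- array(c(ch * jitter_h, ce * jitter_e), c(size, size, 2))
    S <- unclass(stains)
    od <- matrix(conc, ncol = 2) %*% t(S)            # npix x 3
    img <- round(255 * 10^(-od))
    img[img < 0] <- 0
    img[img > 255] <- 255
    list(image = array(img, c(size, size, 3)),
         truth = list(nucleus_count = n_nuc, concentrations = conc,
                      stains = stains))
  })
}

#' Synthetic cohort configuration
#'
#' @param classes list of \code{\link{synthetic_class_spec}} objects.
#' @param patients_per_class,images_per_patient cohort dimensions.
#' @param magnifications subset of 40X/100X/200X/400X, or "none".
#' @param image_size image side in pixels.
#' @param stains ground-truth \code{\link{stain_matrix}}.
#' @param seed integer master seed; every image derives its own seed from it.
#' @return An object of class \code{"synthetic_cohort_config"}.
#' @export
synthetic_cohort_config <- function(classes, patients_per_class = 3L,
                                    images_per_patient = 4L,
                                    magnifications = "none",
                                    image_size = 96L, stains = NULL,
                                    seed = 1L) {
  stopifnot(is.list(classes), length(classes) >= 1,
            all(vapply(classes, inherits, logical(1),
                       "synthetic_class_spec")))
  if (is.null(stains)) stains <- default_stain_reference()$stains
  stopifnot(all(magnifications %in% names(.mag_scale)))
  structure(list(classes = classes,
                 patients_per_class = as.integer(patients_per_class),
                 images_per_patient = as.integer(images_per_patient),
                 magnifications = magnifications,
                 image_size = as.integer(image_size),
                 stains = stains, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic cohort tree on disk
#'
#' Writes PNG images in either the BreakHis-style layout
#' (category/subclass/patient/magnification/image.png) or the class-folder
#' layout (class/image.png), plus \code{manifest.csv} and a
#' \code{truth.json} with per-image ground-truth nucleus counts.
#' Per-class image counts equal
#' \code{patients_per_class * images_per_patient * length(magnifications)}
#' exactly, and output is deterministic for a fixed seed.
#'
#' @param config a \code{\link{synthetic_cohort_config}}.
#' @param out_root output directory (created if missing).
#' @param style tree layout.
#' @return The sample manifest data frame (invisibly also written to
#'   \code{out_root/manifest.csv}).
#' @export
generate_cohort <- function(config, out_root,
                            style = c("breakhis", "class_folder")) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  style <- match.arg(style)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_root)) stop("cannot create output directory ", out_root)
  rows <- list()
  truth <- list()
  counter <- 0L
  for (cls in config$classes) {
    for (p in seq_len(config$patients_per_class)) {
      patient <- sprintf("%s_pt%02d", cls$name, p)
      for (i in seq_len(config$images_per_patient)) {
        for (mag in config$magnifications) {
          counter <- counter + 1L
          gen <- generate_tissue_image(cls, config$stains,
                                       size = config$image_size,
                                       seed = config$seed + counter,
                                       magnification = mag)
          fname <- sprintf("img%02d.png", i)
          rel <- if (style == "breakhis")
            file.path(cls$category, cls$name, patient, mag, fname)
          else
            file.path(cls$name, sprintf("%s_img%02d.png", patient, i))
          path <- file.path(out_root, rel)
          dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
          write_image(gen$image, path)
          image_id <- if (style == "breakhis")
            paste(patient, mag, sprintf("img%02d", i), sep = "_")
          else sprintf("%s_%s_img%02d", cls$name, patient, i)
          rows[[counter]] <- data.frame(
            image_id = image_id, path = path,
            patient_id = if (style == "breakhis") patient else image_id,
            category = if (style == "breakhis") cls$category else "none",
            subclass = cls$name,
            magnification = if (style == "breakhis") mag else "none",
            stringsAsFactors = FALSE)
          truth[[image_id]] <- list(nucleus_count = gen$truth$nucleus_count,
                                    class = cls$name, seed = config$seed + counter)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_root, "manifest.csv"))
  jsonlite::write_json(truth, file.path(out_root, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
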