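# Class-balanced patch budgeting and seeded random patch extraction.
#
# The budget rule assigns each class i a per-image patch count
#   N_i = ceil( mean(x) / x_i * beta ),
# where x_i is the number of images in class i and beta a fixed constant
# (default 32). Classes with many images get few patches per image and vice
# versa, so post-budget class totals N_i * x_i are near-balanced up to
# ceiling error.

#' Per-class patch budget
#'
#' @param class_counts named integer vector: images per class (all > 0).
#' @param beta fixed scale constant; 32 balances an eight-class cohort of a
#'   few hundred images per class to roughly \code{32 * mean(x)} patches
#'   per class.
#' @return An object of class \code{"patch_budget"}: list with
#'   \code{patches_per_image} (named integer vector N_i), \code{beta},
#'   \code{class_counts}, \code{n_classes}.
#' @export
compute_patch_budget <- function(class_counts, beta = 32L) {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts))))
    stop("class_counts must be a named vector")
  if (any(class_counts <= 0))
    stop("empty-class: every class must have at least one image")
  if (beta <= 0) stop("beta must be positive")
  x <- as.numeric(class_counts)
  n_i <- as.integer(ceiling(mean(x) / x * beta))
  names(n_i) <- names(class_counts)
  structure(list(patches_per_image = n_i, beta = as.integer(beta),
                 class_counts = class_counts,
                 n_classes = length(class_counts)),
            class = "patch_budget")
}

#' @export
print.patch_budget <- function(x, ...) {
  cat("Patch budget (beta =", x$beta, ")\n")
  df <- data.frame(class = names(x$patches_per_image),
                   images = as.integer(x$class_counts),
                   patches_per_image = x$patches_per_image,
                   class_total = x$patches_per_image *
                     as.integer(x$class_counts),
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' Extract seeded random patches from one image
#'
#' Draws \code{n} square windows of side \code{size} at uniformly random
#' in-bounds offsets (0-based, half-open \code{[x, x + size)}), fully inside
#' the image; deterministic for a fixed seed. Provenance fields are copied
#' into every record.
#'
#' @param image array (height, width, channels).
#' @param n number of patches.
#' @param size patch side in pixels (default 224).
#' @param seed integer seed.
#' @param image_id,patient_id,class_label,magnification provenance carried
#'   into the records.
#' @return List with \code{records} (data frame: patch_id, source_image_id,
#'   patient_id, class_label, magnification, x, y, size) and \code{patches}
#'   (list of arrays).
#' @export
extract_patches <- function(image, n, size = 224L, seed = 1L,
                            image_id = "img", patient_id = NA_character_,
                            class_label = NA_character_,
                            magnification = "none") {
  d <- dim(image)
  if (d[1] < size || d[2] < size)
    stop("too-small: image ", d[1], "x", d[2],
         " cannot host a ", size, "x", size, " patch")
  n <- as.integer(n)
  offs <- .with_seed(seed, {
    # x spans columns (width), y spans rows (height); 0-based
    data.frame(x = sample.int(d[2] - size + 1L, n, replace = TRUE) - 1L,
               y = sample.int(d[1] - size + 1L, n, replace = TRUE) - 1L)
  })
  patches <- lapply(seq_len(n), function(i)
    image[offs$y[i] + seq_len(size), offs$x[i] + seq_len(size), ,
          drop = FALSE])
  records <- data.frame(
    patch_id = sprintf("%s_p%03d", image_id, seq_len(n)),
    source_image_id = image_id,
    patient_id = patient_id,
    class_label = class_label,
    magnification = magnification,
    x = offs$x, y = offs$y, size = as.integer(size),
    stringsAsFactors = FALSE)
  list(records = records, patches = patches)
}

#' Resize an image to the network input size
#'
#' Bilinear resampling used in whole-image mode (e.g. 700x460 down to
#' 224x224) when patch extraction is disabled.
#'
#' @param image array (height, width, channels).
#' @param out_h,out_w target size in pixels.
#' @return Resized array.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  d <- dim(image)
  # map output pixel centers to input coordinates
  ys <- (seq_len(out_h) - 0.5) * d[1] / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * d[2] / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), d[1] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  x0 <- pmin(pmax(floor(xs), 0), d[2] - 1); x1 <- pmin(x0 + 1, d[2] - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    ch <- image[, , c]
    a <- ch[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- ch[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    e <- ch[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    f <- ch[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    wxm <- rep(wx, each = out_h); wym <- rep(wy, out_w)
    out[, , c] <- matrix((1 - wym) * ((1 - wxm) * a + wxm * b) +
                         wym * ((1 - wxm) * e + wxm * f),
                         nrow = out_h)
  }
  out
}

#' Extract patches for a whole cohort manifest
#'
#' Computes the per-class budget from the manifest, extracts that many
#' patches from every image (seeded per image), writes them as PNG files and
#' returns the patch manifest.
#'
#' @param manifest sample manifest (see \code{\link{scan_breakhis_tree}}).
#' @param out_dir directory for patch PNGs.
#' @param beta budget constant (see \code{\link{compute_patch_budget}}).
#' @param size patch side in pixels.
#' @param seed base seed; each image uses \code{seed + row index}.
#' @return Patch manifest data frame with a \code{path} column.
#' @export
extract_cohort_patches <- function(manifest, out_dir, beta = 32L,
                                   size = 224L, seed = 1L) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  budget <- compute_patch_budget(table_to_counts(manifest$subclass), beta)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- read_image(row$path)
    n <- budget$patches_per_image[[row$subclass]]
    ex <- extract_patches(img, n, size = size, seed = seed + i,
                          image_id = row$image_id,
                          patient_id = row$patient_id,
                          class_label = row$subclass,
                          magnification = row$magnification)
    paths <- file.path(out_dir, paste0(ex$records$patch_id, ".png"))
    for (j in seq_len(n)) write_image(ex$patches[[j]], paths[j])
    ex$records$path <- paths
    out[[i]] <- ex$records
  }
  do.call(rbind, out)
}

table_to_counts <- function(labels) {
  tab <- table(labels)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Read and write 8-bit RGB PNG images
#'
#' Thin wrappers: images live in files as PNG and in memory as
#' (height, width, 3) arrays of 8-bit values in [0, 255].
#'
#' @param path PNG file path.
#' @return \code{read_image}: the pixel array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname read_image
#' @param image array (height, width, 3) of values in [0, 255].
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
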