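# Macenko stain normalization. H&E images are modelled by the Beer-Lambert
# law: in optical-density (OD) space a pixel is a nonnegative mixture of two
# unit stain vectors (hematoxylin, eosin). The stain basis of an image is
# estimated from the principal plane of its tissue-pixel OD cloud; robust
# angular extremes of the projected cloud give the two stain directions.

#' Convert an 8-bit RGB image to optical density
#'
#' \code{OD = -log10((I + 1) / I0)} with \code{I0 = 255}; the +1 guard
#' removes log(0). \code{od_to_rgb} inverts the transform and rounds back to
#' 8-bit; the round trip is lossless up to quantization.
#'
#' @param image array (height, width, 3) of 8-bit values in [0, 255].
#' @return Array of the same shape with OD values.
#' @export
rgb_to_od <- function(image) {
  if (any(image < 0 | image > 255)) stop("pixel values must be in [0, 255]")
  -log10((image + 1) / 255)
}

#' @rdname rgb_to_od
#' @param od array of optical densities.
#' @export
od_to_rgb <- function(od) {
  out <- round(255 * 10^(-od) - 1)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Stain matrix constructor
#'
#' Two unit-norm 3-vectors in OD space, hematoxylin first. Ordering follows
#' the blue-channel OD component: hematoxylin (blue/purple nuclei) absorbs
#' more in blue than eosin does.
#'
#' @param vectors 3 x 2 numeric matrix, one stain vector per column.
#' @return An object of class \code{"stain_matrix"} (a 3 x 2 matrix with
#'   columns \code{hematoxylin}, \code{eosin}).
#' @export
stain_matrix <- function(vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) == 3, ncol(vectors) == 2)
  if (any(vectors < -1e-8)) stop("stain vector components must be nonnegative")
  vectors[vectors < 0] <- 0
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm < 1e-8)) stop("stain vectors must be nonzero")
  vectors <- sweep(vectors, 2, nrm, "/")
  if (vectors[3, 1] < vectors[3, 2]) vectors <- vectors[, 2:1]
  colnames(vectors) <- c("hematoxylin", "eosin")
  structure(vectors, class = c("stain_matrix", "matrix"))
}

#' Default reference stain basis
#'
#' The widely used hematoxylin (0.65, 0.70, 0.29) / eosin (0.07, 0.99, 0.11)
#' OD vectors (normalized), with reference maximum concentrations
#' (1.9, 1.0).
#'
#' @return List with elements \code{stains} (a \code{\link{stain_matrix}})
#'   and \code{max_c} (length-2 numeric).
#' @export
default_stain_reference <- function() {
  list(stains = stain_matrix(cbind(c(0.65, 0.70, 0.29),
                                   c(0.07, 0.99, 0.11))),
       max_c = c(1.9, 1.0))
}

#' Estimate the stain matrix of an H&E image (Macenko)
#'
#' Pixels whose OD vector magnitude exceeds \code{od_threshold} are treated
#' as tissue. The two leading eigenvectors of the tissue OD covariance span
#' the stain plane; each pixel's angle within that plane is computed and the
#' \code{angle_percentile} / (100 - \code{angle_percentile}) extreme
#' directions, mapped back to OD space, sign-corrected and normalized, are
#' the stain vectors.
#'
#' @param image array (height, width, 3), 8-bit RGB.
#' @param od_threshold OD magnitude below which a pixel is background.
#' @param angle_percentile robust percentile for the angular extremes.
#' @return A \code{\link{stain_matrix}}.
#' @export
estimate_stain_matrix <- function(image, od_threshold = 0.15,
                                  angle_percentile = 1) {
  od <- rgb_to_od(image)
  odm <- matrix(od, ncol = 3)
  keep <- sqrt(rowSums(odm^2)) > od_threshold
  if (sum(keep) < 100)
    stop("no-tissue: fewer than 100 pixels above the OD threshold")
  tissue <- odm[keep, , drop = FALSE]
  ev <- eigen(stats::cov(tissue), symmetric = TRUE)
  # The rank test must not mistake 8-bit quantization noise (OD variance
  # ~1e-6 per channel) for a second stain: require the second eigenvalue to
  # clear both an absolute floor above that noise and a relative fraction of
  # the leading eigenvalue.
  if (ev$values[2] < 1e-5 || ev$values[2] < 1e-3 * ev$values[1])
    stop("degenerate-stain: tissue OD cloud has rank < 2 ",
         "(single stain or uniform color)")
  basis <- ev$vectors[, 1:2, drop = FALSE]
  # orient the plane so projections are predominantly positive
  for (j in 1:2) if (sum(tissue %*% basis[, j]) < 0) basis[, j] <- -basis[, j]
  proj <- tissue %*% basis
  ang <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(ang, c(angle_percentile, 100 - angle_percentile) / 100,
                        names = FALSE)
  v1 <- basis %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- basis %*% c(cos(qs[2]), sin(qs[2]))
  fix <- function(v) {
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    v
  }
  stain_matrix(cbind(fix(v1), fix(v2)))
}

#' Per-pixel stain concentrations
#'
#' Least-squares decomposition of each pixel's OD vector onto the two stain
#' vectors; negative solutions are clipped to zero.
#'
#' @param od array (height, width, 3) of optical densities.
#' @param stains a \code{\link{stain_matrix}}.
#' @return Array (height, width, 2) of nonnegative concentrations
#'   (hematoxylin, eosin), class \code{"concentration_map"}.
#' @export
compute_concentrations <- function(od, stains) {
  stopifnot(inherits(stains, "stain_matrix"))
  d <- dim(od)
  odm <- t(matrix(od, ncol = 3))                    # 3 x npix
  S <- unclass(stains)
  C <- solve(crossprod(S), crossprod(S, odm))       # 2 x npix
  C[C < 0] <- 0
  out <- array(t(C), dim = c(d[1], d[2], 2))
  class(out) <- c("concentration_map", class(out))
  out
}

#' Normalize an image onto a reference stain basis
#'
#' Estimates the source stain matrix, decomposes the image into
#' concentrations, rescales each stain's concentrations so its 99th
#' percentile maps to the reference maximum, and re-renders through the
#' reference basis: \code{I = I0 * 10^(-reference \%*\% c)}. Applying the
#' transform twice is idempotent up to quantization.
#'
#' @param image array (height, width, 3), 8-bit RGB.
#' @param reference reference \code{\link{stain_matrix}}; defaults to
#'   \code{\link{default_stain_reference}}.
#' @param reference_max_c target maximum concentration per stain.
#' @param od_threshold,angle_percentile passed to
#'   \code{\link{estimate_stain_matrix}}.
#' @param scale_percentile percentile of the source concentrations mapped to
#'   \code{reference_max_c}.
#' @return Normalized 8-bit RGB array, same shape as the input.
#' @export
normalize_image <- function(image, reference = NULL, reference_max_c = NULL,
                            od_threshold = 0.15, angle_percentile = 1,
                            scale_percentile = 99) {
  if (is.null(reference) || is.null(reference_max_c)) {
    ref <- default_stain_reference()
    if (is.null(reference)) reference <- ref$stains
    if (is.null(reference_max_c)) reference_max_c <- ref$max_c
  }
  stopifnot(inherits(reference, "stain_matrix"))
  src <- estimate_stain_matrix(image, od_threshold, angle_percentile)
  conc <- compute_concentrations(rgb_to_od(image), src)
  d <- dim(image)
  cm <- t(matrix(conc, ncol = 2))                   # 2 x npix
  src_max <- apply(cm, 1, stats::quantile, probs = scale_percentile / 100)
  src_max[src_max < 1e-8] <- 1e-8
  cm <- cm * (reference_max_c / src_max)
  od_new <- unclass(reference) %*% cm               # 3 x npix
  # od_to_rgb inverts rgb_to_od exactly (including the +1 guard), which
  # makes repeated normalization a fixed point up to quantization
  array(t(od_to_rgb(od_new)), dim = d)
}

#' Serialize a stain matrix
#'
#' Written as a 6-number JSON document (two stain vectors of 3 OD
#' components, hematoxylin first).
#'
#' @param stains a \code{\link{stain_matrix}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_stain_matrix <- function(stains, path) {
  stopifnot(inherits(stains, "stain_matrix"))
  jsonlite::write_json(list(hematoxylin = unclass(stains)[, 1],
                            eosin = unclass(stains)[, 2]),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_stain_matrix
#' @export
read_stain_matrix <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_matrix(cbind(doc$hematoxylin, doc$eosin))
}

#' Angular distance between stain vectors
#'
#' Degrees between two OD-space direction vectors; the stain-recovery
#' property asks for < 2 degrees against the generator's ground truth.
#'
#' @param u,v numeric 3-vectors (need not be normalized).
#' @return Angle in degrees.
#' @export
stain_angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}
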