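#' Binarize a micrograph into a fiber mask
#'
#' Converts an RGB image to luminance and thresholds it under the
#' darker-fiber convention: pixels strictly darker than the threshold become
#' foreground. The default threshold is Otsu's, appropriate because synthetic
#' micrographs are strongly bimodal (dark fibers on a light background).
#'
#' @param image A `H x W` grayscale matrix or `H x W x 3` RGB array with
#'   values in `[0, 1]` (values in 0--255 are rescaled).
#' @param threshold Intensity threshold in `[0, 1]`; `NULL` (default) uses
#'   Otsu's method on the luminance channel.
#' @return Integer 0/1 matrix (1 = fiber).
#' @export
binarize <- function(image, threshold = NULL) {
  lum <- to_luminance(image)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(lum))
  } else if (threshold > 1) {
    threshold <- threshold / 255
  }
  mask <- (lum < threshold) * 1L
  storage.mode(mask) <- "integer"
  mask
}

to_luminance <- function(image) {
  if (length(dim(image)) == 3) {
    lum <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
      0.0722 * image[, , 3]
  } else {
    lum <- image
  }
  if (max(lum) > 1) lum <- lum / 255
  lum
}

#' Exact Euclidean distance transform
#'
#' For every foreground pixel returns the Euclidean distance from its centre
#' to the centre of the nearest background pixel,
#' `min over background (x2, y2) of sqrt((x1 - x2)^2 + (y1 - y2)^2)`;
#' background pixels map to 0. The implementation is the exact (not chamfer)
#' two-pass lower-envelope algorithm on squared distances.
#'
#' @param mask Integer/logical matrix; nonzero = foreground.
#' @return Numeric matrix of distances (pixel units).
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
#' euclidean_distance_transform(m)  # ring 1, centre 2
euclidean_distance_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  storage.mode(m) <- "integer"
  if (all(m == 1L))
    stop("mask has no background pixel; distance is undefined")
  if (all(m == 0L)) return(matrix(0, nrow(m), ncol(m)))
  edt_cpp(m)
}

#' Normalization scale of distance-map labels
#'
#' A rasterized straight band of odd width `w` attains a maximum distance of
#' `(w + 1) / 2` at its centre row, so labels are normalized by
#' `(max_diameter + 1) / 2` (5.0 for the default 3--9 px diameters) to put
#' (non-overlapping) fibers in `[0, 1]`.
#'
#' @param max_diameter Largest configured fiber diameter (pixels).
#' @return The divisor applied to raw distance maps.
#' @export
label_scale <- function(max_diameter = 9) (max_diameter + 1) / 2

#' Distance-map regression label for a synthetic sample
#'
#' Applies the Euclidean distance transform to the sample's ground-truth
#' mask; optionally rescales to `[0, 1]` by [label_scale()] (values above 1,
#' which only arise inside fiber overlaps, are clipped).
#'
#' @param sample A `synthetic_sample` from [compose_micrograph()], or a 0/1
#'   mask matrix.
#' @param normalize Rescale to `[0, 1]` (default `TRUE`).
#' @param max_diameter Diameter upper bound used for the scale (default 9).
#' @return Numeric matrix: the regression target.
#' @export
make_label <- function(sample, normalize = TRUE, max_diameter = 9) {
  mask <- if (inherits(sample, "synthetic_sample")) sample$mask else sample
  map <- euclidean_distance_transform(mask)
  if (normalize) map <- pmin(map / label_scale(max_diameter), 1)
  map
}
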