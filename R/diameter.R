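#' Segment fibers from a distance map
#'
#' Thresholds the map (foreground = values strictly above `threshold`) and
#' labels 8-connected components. On predicted maps a small positive
#' threshold suppresses regression noise; on exact maps 0 is appropriate.
#'
#' @param map Numeric distance-map matrix.
#' @param threshold Foreground threshold (>= 0).
#' @return List with `mask` (0/1 integer matrix), `labels` (integer matrix
#'   of component ids) and `n_components`.
#' @export
segment_from_distance_map <- function(map, threshold = 0) {
  stopifnot(is.matrix(map), threshold >= 0)
  mask <- (map > threshold) * 1L
  storage.mode(mask) <- "integer"
  labels <- label_components_cpp(mask)
  list(mask = mask, labels = labels, n_components = max(labels))
}

#' Extract the medial ridge of one fiber component
#'
#' Thins the component to a one-pixel skeleton (the medial curve whose
#' distance-map values are fiber half-widths) and prunes short spurs by
#' iteratively removing endpoint pixels.
#'
#' @param map The distance map the component came from.
#' @param component 0/1 matrix selecting one connected component.
#' @param prune Number of endpoint-erosion passes (default 2).
#' @return Matrix of ridge pixel coordinates (`row`, `col`, 1-based) with
#'   attribute `values` (the map values there); 0 rows when the component is
#'   too small to skeletonize, with attribute `flagged = TRUE`.
#' @export
extract_ridge <- function(map, component, prune = 2L) {
  stopifnot(identical(dim(map), dim(component)))
  comp <- (component != 0) * 1L
  storage.mode(comp) <- "integer"
  if (sum(comp) == 0) stop("empty component")
  skel <- thin_cpp(comp)
  for (i in seq_len(prune)) {
    if (sum(skel) <= 1) break
    skel <- remove_endpoints(skel)
  }
  idx <- which(skel == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  colnames(idx) <- c("row", "col")
  attr(idx, "values") <- map[idx]
  idx
}

remove_endpoints <- function(skel) {
  n <- nrow(skel); p <- ncol(skel)
  padded <- matrix(0L, n + 2, p + 2)
  padded[2:(n + 1), 2:(p + 1)] <- skel
  nb <- matrix(0L, n, p)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- nb + padded[2:(n + 1) + di, 2:(p + 1) + dj]
  }
  out <- skel
  out[skel == 1L & nb <= 1L] <- 0L
  # never erase the whole skeleton
  if (sum(out) == 0) skel else out
}

#' Estimate one fiber's diameter from its ridge radii
#'
#' Ridge distance values are fiber half-widths, so the estimate is
#' `2 * r - correction` with `r` an upper quantile of the ridge radii. The
#' default 0.9 quantile with a 0.2 px correction is calibrated once against
#' rasterized straight bands over all orientations (thinning skirts pixels
#' slightly off the deepest row on oblique fibers, which biases the median
#' low; the upper quantile tracks the true half-width and the fixed
#' correction removes the residual grid offset). Ridge pixels whose value
#' exceeds 1.5x the modal ridge value are discarded as crossing artifacts
#' before aggregation. Estimates below one pixel are clamped to 1 and
#' flagged.
#'
#' @param radii Numeric vector of ridge distance values (> 0), e.g. the
#'   `values` attribute of [extract_ridge()].
#' @param calibration Optional scale factor from pixels to micrometres.
#' @param stat Aggregator of ridge radii: `"q90"` (default, calibrated),
#'   `"median"` or `"mean"`.
#' @param correction Fixed grid-offset correction in pixels (default 0.2,
#'   calibrated jointly with the default `stat`).
#' @param crossing_filter Drop ridge values above 1.5x the modal value.
#' @return An object of class `fiber_measurement`: `diameter_px`,
#'   `diameter_um` (or `NA`), `n_ridge`, `radii`, `flagged`.
#' @export
estimate_diameter <- function(radii, calibration = NULL,
                              stat = c("q90", "median", "mean"),
                              correction = 0.2,
                              crossing_filter = TRUE) {
  stat <- match.arg(stat)
  if (length(radii) == 0) stop("empty ridge")
  stopifnot(all(radii > 0))
  kept <- radii
  if (crossing_filter && length(radii) > 2) {
    modal <- modal_value(radii)
    kept <- radii[radii <= 1.5 * modal]
    if (length(kept) == 0) kept <- radii
  }
  r <- switch(stat,
              q90 = stats::quantile(kept, 0.9, names = FALSE),
              median = median(kept),
              mean = mean(kept))
  d <- 2 * r - correction
  flagged <- d < 1
  if (flagged) d <- 1
  structure(list(
    diameter_px = d,
    diameter_um = if (is.null(calibration)) NA_real_ else d * calibration,
    n_ridge = length(radii),
    radii = radii,
    flagged = flagged
  ), class = "fiber_measurement")
}

modal_value <- function(x) {
  # mode of half-pixel-rounded values (EDT values cluster on a lattice)
  r <- round(2 * x) / 2
  ux <- sort(unique(r))
  ux[which.max(tabulate(match(r, ux)))]
}

#' Mean fiber diameter over an image
#'
#' @param measurements List of `fiber_measurement` objects (or the result of
#'   [measure_fibers()]).
#' @param units `"px"` or `"um"`.
#' @return Arithmetic mean of the estimated diameters.
#' @export
mean_fiber_diameter <- function(measurements, units = c("px", "um")) {
  units <- match.arg(units)
  if (!is.null(measurements$per_fiber))
    measurements <- measurements$per_fiber
  if (length(measurements) == 0) stop("no measurements")
  field <- if (units == "px") "diameter_px" else "diameter_um"
  mean(vapply(measurements, function(m) m[[field]], numeric(1)))
}

#' Measure every fiber in a distance map
#'
#' Segments the map, extracts each component's medial ridge and estimates
#' per-fiber and mean diameters -- the morphometric application the
#' distance-map regression serves.
#'
#' @param map Distance map (ground truth or prediction), in pixel units;
#'   multiply a normalized prediction by [label_scale()] first, or use
#'   `predict(fit, img, units = "pixels")`.
#' @param threshold Segmentation threshold (see
#'   [segment_from_distance_map()]).
#' @param calibration Optional px-to-um factor.
#' @param min_pixels Ignore components smaller than this (default 4).
#' @param ... Passed to [estimate_diameter()].
#' @return List with `per_fiber` (list of `fiber_measurement`),
#'   `mean_diameter_px`, `mean_diameter_um` and `n_fibers`.
#' @export
measure_fibers <- function(map, threshold = 0, calibration = NULL,
                           min_pixels = 4L, ...) {
  seg <- segment_from_distance_map(map, threshold)
  out <- list()
  for (comp in seq_len(seg$n_components)) {
    cm <- (seg$labels == comp) * 1L
    if (sum(cm) < min_pixels) next
    ridge <- extract_ridge(map, cm)
    vals <- attr(ridge, "values")
    if (is.null(vals) || length(vals) == 0) next
    out[[length(out) + 1L]] <-
      estimate_diameter(vals, calibration = calibration, ...)
  }
  list(per_fiber = out,
       n_fibers = length(out),
       mean_diameter_px = if (length(out))
         mean_fiber_diameter(out, "px") else NA_real_,
       mean_diameter_um = if (length(out) && !is.null(calibration))
         mean_fiber_diameter(out, "um") else NA_real_)
}
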