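#' Simulation settings for synthetic fiber micrographs
#'
#' Defines the geometry and noise model of the synthetic micrograph generator.
#' Fibers are carrier lines drawn by mu-randomness -- a line is specified by
#' the perpendicular distance `d` from the image centre `O` and the angular
#' position `alpha` of that perpendicular, with `d` limited to the image
#' diagonal -- and curved by a sinusoid whose wavelength spans the carrier
#' chord. Each fiber gets its own gray level, per-pixel Gaussian noise, and a
#' global Gaussian noise field is added to the whole micrograph.
#'
#' @param height,width Canvas size in pixels (default 189 x 189, the
#'   resolution of OFDA screenshot micrographs).
#' @param fiber_count_range Integer range of fibers per image (default 1--15).
#' @param diameter_range Integer range of fiber thickness in pixels
#'   (default 3--9).
#' @param amplitude_frac_range Sinusoid amplitude as a fraction of the carrier
#'   chord length, drawn uniformly (default 0--0.1).
#' @param wavelength_periods Number of full sinusoid periods spanning the
#'   chord (default 1).
#' @param gray_range Integer range of fiber base intensities on the 0--255
#'   scale (default 40--200; fibers are darker than the background).
#' @param background_gray Background intensity, 0--255 (default 230).
#' @param pixel_noise_sigma Std.\ dev.\ of per-pixel Gaussian noise added to
#'   each fiber's pixels, intensity units (default 8).
#' @param global_noise_sigma Std.\ dev.\ of the additive Gaussian field applied
#'   to the whole micrograph (default 5).
#' @param min_chord_factor A drawn fiber is rejected and redrawn unless its
#'   visible centerline chord is at least this multiple of its diameter and
#'   clears every border by at least one diameter (default 2).
#' @param centerline_step Arc-length sampling step of the centerline in
#'   pixels (default 0.25).
#' @return An object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(height = 64, width = 64)
#' s <- compose_micrograph(cfg, seed = 1)
#' length(s$specs)
simulation_config <- function(height = 189, width = 189,
                              fiber_count_range = c(1L, 15L),
                              diameter_range = c(3L, 9L),
                              amplitude_frac_range = c(0, 0.1),
                              wavelength_periods = 1,
                              gray_range = c(40L, 200L),
                              background_gray = 230,
                              pixel_noise_sigma = 8,
                              global_noise_sigma = 5,
                              min_chord_factor = 2,
                              centerline_step = 0.25) {
  stopifnot(height >= 16, width >= 16)
  check_range <- function(r, what) {
    if (length(r) != 2L || r[1] > r[2])
      stop(sprintf("'%s' must be a nonempty range c(min, max)", what))
  }
  check_range(fiber_count_range, "fiber_count_range")
  check_range(diameter_range, "diameter_range")
  check_range(amplitude_frac_range, "amplitude_frac_range")
  check_range(gray_range, "gray_range")
  stopifnot(fiber_count_range[1] >= 1, diameter_range[1] >= 1,
            amplitude_frac_range[1] >= 0, pixel_noise_sigma >= 0,
            global_noise_sigma >= 0, wavelength_periods > 0,
            centerline_step > 0)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    fiber_count_range = as.integer(fiber_count_range),
    diameter_range = as.integer(diameter_range),
    amplitude_frac_range = as.numeric(amplitude_frac_range),
    wavelength_periods = wavelength_periods,
    gray_range = as.integer(gray_range),
    background_gray = background_gray,
    pixel_noise_sigma = pixel_noise_sigma,
    global_noise_sigma = global_noise_sigma,
    min_chord_factor = min_chord_factor,
    centerline_step = centerline_step
  ), class = "simulation_config")
}

#' Draw one fiber specification by mu-randomness
#'
#' Samples a carrier line (perpendicular distance `d` uniform on
#' `[0, diagonal]`, angle `alpha` uniform on `[0, 2*pi)`), a sinusoid
#' amplitude (uniform fraction of the chord length, stored in pixels), an
#' integer diameter and a gray level, using the current RNG state.
#'
#' @param config A [simulation_config()].
#' @return An object of class `fiber_spec` with fields `d`, `alpha`,
#'   `amplitude`, `diameter`, `gray`.
#' @export
sample_fiber_line <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  diag_len <- sqrt(config$height^2 + config$width^2)
  d <- runif(1, 0, diag_len)
  alpha <- runif(1, 0, 2 * pi)
  diameter <- sample_int_range(config$diameter_range)
  gray <- sample_int_range(config$gray_range)
  spec <- structure(list(d = d, alpha = alpha, amplitude = 0,
                         diameter = diameter, gray = gray),
                    class = "fiber_spec")
  chord <- carrier_chord(spec, config)
  frac <- runif(1, config$amplitude_frac_range[1],
                config$amplitude_frac_range[2])
  if (!is.null(chord)) spec$amplitude <- frac * (chord$t1 - chord$t0)
  spec
}

sample_int_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq.int(r[1], r[2]), 1L)
}

# Clip the carrier line to the pixel-centre rectangle [0, p-1] x [0, n-1].
# Returns NULL when the line misses the canvas, otherwise the foot point F,
# line direction u and the parameter interval [t0, t1] (Liang-Barsky).
carrier_chord <- function(spec, config) {
  n <- config$height; p <- config$width
  cx <- (p - 1) / 2; cy <- (n - 1) / 2
  fx <- cx + spec$d * cos(spec$alpha)
  fy <- cy + spec$d * sin(spec$alpha)
  ux <- -sin(spec$alpha); uy <- cos(spec$alpha)
  t0 <- -Inf; t1 <- Inf
  bounds <- list(c(-ux, fx - 0), c(ux, (p - 1) - fx),
                 c(-uy, fy - 0), c(uy, (n - 1) - fy))
  for (b in bounds) {
    den <- b[1]; num <- b[2]   # constraint: den * t <= num
    if (abs(den) < 1e-12) {
      if (num < 0) return(NULL)
    } else if (den > 0) {
      t1 <- min(t1, num / den)
    } else {
      t0 <- max(t0, num / den)
    }
  }
  if (!is.finite(t0) || !is.finite(t1) || t0 >= t1) return(NULL)
  list(fx = fx, fy = fy, ux = ux, uy = uy, t0 = t0, t1 = t1)
}

#' Compute a fiber centerline polyline
#'
#' Places a sinusoid of the spec's amplitude along the mu-randomness carrier
#' line: one full wavelength (times `wavelength_periods`) spans the chord the
#' line cuts through the canvas, and the wave is rotated by `alpha` and
#' translated to the carrier position. Points are sampled densely
#' (`centerline_step` pixels apart along the carrier).
#'
#' @param spec A [sample_fiber_line()] result (class `fiber_spec`).
#' @param config A [simulation_config()].
#' @return A numeric matrix with columns `(row, col)` (0-based pixel-centre
#'   coordinates). When the carrier misses the canvas, a 0-row matrix with
#'   attribute `degenerate = TRUE`.
#' @export
fiber_centerline <- function(spec, config) {
  stopifnot(inherits(spec, "fiber_spec"), inherits(config, "simulation_config"))
  ch <- carrier_chord(spec, config)
  if (is.null(ch)) {
    out <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  len <- ch$t1 - ch$t0
  t <- seq(ch$t0, ch$t1, by = config$centerline_step)
  phase <- 2 * pi * config$wavelength_periods * (t - ch$t0) / len
  off <- spec$amplitude * sin(phase)
  # perpendicular direction (towards increasing d)
  vx <- cos(spec$alpha); vy <- sin(spec$alpha)
  x <- ch$fx + t * ch$ux + off * vx
  y <- ch$fy + t * ch$uy + off * vy
  cbind(row = y, col = x)
}

#' Rasterize a centerline to a binary fiber mask
#'
#' Marks every pixel whose centre lies strictly within `diameter/2 - 0.2` of
#' the centerline (the 0.2 px calibration compensates pixel-grid anisotropy
#' so the rendered thickness, measured by the band's maximum distance
#' transform `v`, satisfies `2v - 1 <= diameter <= 2v + 1` at every
#' orientation). Anti-aliasing is never applied to masks.
#'
#' @param centerline Matrix of `(row, col)` points from [fiber_centerline()].
#' @param diameter Fiber thickness in pixels (>= 1).
#' @param canvas Integer vector `c(height, width)`.
#' @return An integer `height x width` matrix of 0/1.
#' @export
rasterize_fiber <- function(centerline, diameter, canvas) {
  stopifnot(diameter >= 1, length(canvas) == 2)
  if (nrow(centerline) == 0)
    return(matrix(0L, canvas[1], canvas[2]))
  rasterize_points_cpp(centerline, diameter, as.integer(canvas[1]),
                       as.integer(canvas[2]))
}

#' Compose one synthetic fiber micrograph
#'
#' Draws `k` fibers (`k` uniform in `fiber_count_range`), paints them in
#' painter's order (later fibers overwrite earlier ones at overlaps), each in
#' its own gray level with per-pixel Gaussian noise, adds a global Gaussian
#' noise field, and returns the RGB image together with the ground-truth
#' union mask, the per-fiber masks and the fiber specs. Fibers whose carrier
#' chord misses the canvas or leaves too small a visible segment are redrawn.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed (sets the RNG before drawing).
#' @return An object of class `synthetic_sample`: list with `image`
#'   (`height x width x 3` array in `[0, 1]`), `mask` (0/1 integer matrix),
#'   `per_fiber_masks` (list of 0/1 matrices) and `specs` (list of
#'   `fiber_spec`).
#' @export
compose_micrograph <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$height; p <- config$width
  k <- sample_int_range(config$fiber_count_range)
  specs <- vector("list", k)
  masks <- vector("list", k)
  grays <- integer(0)
  img <- matrix(config$background_gray, n, p)
  for (f in seq_len(k)) {
    for (try in seq_len(200L)) {
      spec <- sample_fiber_line(config)
      cl <- fiber_centerline(spec, config)
      if (nrow(cl) == 0) next
      if (!fiber_visible(cl, spec$diameter, n, p, config$min_chord_factor,
                         config$centerline_step))
        next
      m <- rasterize_fiber(cl, spec$diameter, c(n, p))
      if (sum(m) == 0) next
      if (spec$gray %in% grays)        # each fiber gets a distinct gray
        spec$gray <- resample_gray(config, grays)
      grays <- c(grays, spec$gray)
      specs[[f]] <- spec
      masks[[f]] <- m
      break
    }
    if (is.null(specs[[f]]))
      stop("could not place a visible fiber after 200 attempts")
    idx <- masks[[f]] == 1L
    img[idx] <- specs[[f]]$gray
    if (config$pixel_noise_sigma > 0)
      img[idx] <- img[idx] + rnorm(sum(idx), 0, config$pixel_noise_sigma)
  }
  if (config$global_noise_sigma > 0)
    img <- img + matrix(rnorm(n * p, 0, config$global_noise_sigma), n, p)
  img <- pmin(pmax(img, 0), 255) / 255
  union_mask <- Reduce(function(a, b) pmax(a, b), masks)
  storage.mode(union_mask) <- "integer"
  structure(list(
    image = array(c(img, img, img), dim = c(n, p, 3)),
    mask = union_mask,
    per_fiber_masks = masks,
    specs = specs
  ), class = "synthetic_sample")
}

# A fiber is accepted when its visible chord is long enough and at least one
# centerline point keeps a full diameter of clearance from every border, so
# that the rasterized fiber contains its full cross-section somewhere.
fiber_visible <- function(cl, diameter, n, p, min_chord_factor, step) {
  chord <- nrow(cl) * step
  if (chord < min_chord_factor * diameter) return(FALSE)
  margin <- pmin(cl[, 1], (n - 1) - cl[, 1], cl[, 2], (p - 1) - cl[, 2])
  any(margin >= diameter)
}

resample_gray <- function(config, used) {
  pool <- setdiff(seq.int(config$gray_range[1], config$gray_range[2]), used)
  if (length(pool) == 0) stop("gray_range exhausted")
  if (length(pool) == 1) pool else sample(pool, 1L)
}

#' Generate a reproducible synthetic dataset
#'
#' @param config A [simulation_config()].
#' @param count Number of micrographs (>= 1).
#' @param seed Optional integer seed; the whole dataset is a single RNG
#'   stream, so a fixed seed reproduces every sample bit-for-bit.
#' @param dir Optional output directory: writes `sample_###.png` (RGB
#'   micrograph), `sample_###_mask.png` and a `manifest.json` listing the
#'   fiber specs and the seed.
#' @return Invisibly for `dir != NULL`, otherwise a list of
#'   `synthetic_sample` objects (always returned).
#' @export
generate_dataset <- function(config, count, seed = NULL, dir = NULL) {
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(seed)
  samples <- lapply(seq_len(count), function(i) compose_micrograph(config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    entries <- vector("list", count)
    for (i in seq_along(samples)) {
      stem <- sprintf("sample_%03d", i)
      png::writePNG(samples[[i]]$image, file.path(dir, paste0(stem, ".png")))
      png::writePNG(samples[[i]]$mask + 0.0,
                    file.path(dir, paste0(stem, "_mask.png")))
      entries[[i]] <- list(
        file = paste0(stem, ".png"),
        specs = lapply(samples[[i]]$specs, unclass)
      )
    }
    manifest <- list(seed = seed, count = count,
                     config = unclass(config), samples = entries)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  samples
}
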