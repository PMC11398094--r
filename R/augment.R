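#' Augmentation specification
#'
#' The six supported random transforms: horizontal/vertical flips and
#' 90-degree rotations are geometric and applied identically to the image
#' and its distance-map label (the Euclidean distance map is exactly
#' equivariant under these); Gaussian blur, posterization and autocontrast
#' are photometric and touch the image only.
#'
#' @param transforms Ordered subset of `c("horizontal_flip",
#'   "vertical_flip", "rotation", "gaussian_blur", "posterization",
#'   "autocontrast")`.
#' @param prob Per-transform application probability (default 0.5).
#' @param blur_sigma_range Uniform range of the blur kernel sigma in pixels.
#' @param posterize_bits Bits kept per channel by posterization.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(transforms = c("horizontal_flip",
                                             "vertical_flip", "rotation",
                                             "gaussian_blur",
                                             "posterization",
                                             "autocontrast"),
                              prob = 0.5,
                              blur_sigma_range = c(0.5, 1.5),
                              posterize_bits = 4L) {
  allowed <- c("horizontal_flip", "vertical_flip", "rotation",
               "gaussian_blur", "posterization", "autocontrast")
  bad <- setdiff(transforms, allowed)
  if (length(bad))
    stop("unknown transform(s): ", paste(bad, collapse = ", "))
  stopifnot(prob >= 0, prob <= 1)
  structure(list(transforms = transforms, prob = prob,
                 blur_sigma_range = blur_sigma_range,
                 posterize_bits = as.integer(posterize_bits)),
            class = "augmentation_spec")
}

flip_h <- function(x) {
  if (length(dim(x)) == 3) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}
flip_v <- function(x) {
  if (length(dim(x)) == 3) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  else x[rev(seq_len(nrow(x))), , drop = FALSE]
}
rot90k <- function(x, k) {
  k <- k %% 4L
  if (k == 0) return(x)
  r1 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  f <- function(m) { for (i in seq_len(k)) m <- r1(m); m }
  if (length(dim(x)) == 3) {
    slices <- lapply(seq_len(dim(x)[3]), function(c) f(x[, , c]))
    array(unlist(slices), dim = c(dim(slices[[1]]), dim(x)[3]))
  } else f(x)
}

#' Apply a random augmentation to an (image, label) pair
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param label `H x W` distance-map matrix (spatially aligned).
#' @param spec An [augmentation_spec()]; draws use the current RNG state.
#' @return List with transformed `image` and `label`.
#' @export
augment <- function(image, label, spec = augmentation_spec()) {
  stopifnot(inherits(spec, "augmentation_spec"),
            all(dim(image)[1:2] == dim(label)[1:2]))
  for (tr in spec$transforms) {
    if (runif(1) >= spec$prob) next
    switch(tr,
      horizontal_flip = { image <- flip_h(image); label <- flip_h(label) },
      vertical_flip = { image <- flip_v(image); label <- flip_v(label) },
      rotation = {
        k <- sample(1:3, 1)
        image <- rot90k(image, k); label <- rot90k(label, k)
      },
      gaussian_blur = {
        s <- runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
        image <- gblur_array(image, s)
      },
      posterization = {
        levels <- 2^spec$posterize_bits
        image <- floor(image * (levels - 1) + 0.5) / (levels - 1)
      },
      autocontrast = {
        for (c in seq_len(dim(image)[3])) {
          ch <- image[, , c]
          rng <- range(ch)
          if (diff(rng) > 0) image[, , c] <- (ch - rng[1]) / diff(rng)
        }
      })
  }
  list(image = image, label = label)
}

gblur_array <- function(image, sigma) {
  out <- image
  for (c in seq_len(dim(image)[3]))
    out[, , c] <- as.matrix(EBImage::gblur(EBImage::Image(image[, , c]),
                                           sigma = sigma))
  pmin(pmax(out, 0), 1)
}

#' Effective dataset size under augmentation
#'
#' With `T` random transforms the effective number of distinct training
#' samples is `Initial_Data_Size * 2^T`; transforms are applied on the fly
#' each epoch rather than materialized, and this function provides the
#' accounting.
#'
#' @param initial_size Base number of training images.
#' @param n_transforms Number of transforms `T` in the augmentation set.
#' @return The effective dataset size.
#' @export
effective_dataset_size <- function(initial_size, n_transforms)
  initial_size * 2^n_transforms

#' Fuse real and synthetic training sets
#'
#' Concatenates the two sample lists and shuffles deterministically under
#' the seed. Either list may be empty (synthetic-only or real-only
#' ablations); both empty is an error.
#'
#' @param real,synthetic Lists of training samples.
#' @param seed Integer seed for the shuffle.
#' @return A shuffled list.
#' @export
fuse_training_sets <- function(real, synthetic, seed = 1L) {
  pool <- c(real, synthetic)
  if (length(pool) == 0) stop("both training sets are empty")
  set.seed(seed)
  pool[sample.int(length(pool))]
}
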