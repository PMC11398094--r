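# Independent oracles and shared fixtures, kept free of the code paths they
# check.

# O(n^2 p^2) all-pairs Euclidean distance transform
bf_edt <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  out <- matrix(0, n, p)
  bg <- which(mask == 0, arr.ind = TRUE)
  fg <- which(mask != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[q, 1])^2 + (bg[, 2] - fg[q, 2])^2
    out[fg[q, 1], fg[q, 2]] <- sqrt(min(d2))
  }
  out
}

# max distance transform of a mask padded with a background ring, so fibers
# clipped by the canvas border are measured by their true thickness
pad_edt_max <- function(m) {
  pm <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pm[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  max(euclidean_distance_transform(pm))
}

# desk-scale study conditions: 64 x 64 canvas with the fiber count scaled to
# the default 189 x 189 density (15 * 64^2 / 189^2 ~ 1.7 -> 1..5 fibers)
desk_cfg <- function(...)
  simulation_config(height = 64, width = 64, fiber_count_range = c(1, 5),
                    ...)

tiny_cfg <- function(...)
  simulation_config(height = 32, width = 32, fiber_count_range = c(1, 3),
                    ...)

# straight horizontal band mask of given width starting at row0
make_band <- function(n, p, row0, width) {
  m <- matrix(0L, n, p)
  m[row0:(row0 + width - 1), ] <- 1L
  m
}

# single straight isolated fiber sample (no curvature, no noise)
straight_cfg <- function(height = 189, width = 189)
  simulation_config(height = height, width = width,
                    fiber_count_range = c(1, 1),
                    amplitude_frac_range = c(0, 0),
                    pixel_noise_sigma = 0, global_noise_sigma = 0)

training_pairs <- function(samples)
  lapply(samples, function(s) list(image = s$image, label = make_label(s)))
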