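test_that("mu-randomness fiber specs respect the configured distributions", {
  cfg <- simulation_config()
  diag_len <- sqrt(cfg$height^2 + cfg$width^2)
  set.seed(11)
  for (i in 1:200) {
    sp <- sample_fiber_line(cfg)
    expect_gte(sp$d, 0)
    expect_lte(sp$d, diag_len)
    expect_gte(sp$alpha, 0)
    expect_lt(sp$alpha, 2 * pi)
    expect_true(sp$diameter %in% 3:9)
    expect_true(sp$gray %in% 40:200)
    expect_gte(sp$amplitude, 0)
  }
  set.seed(5); a <- replicate(5, sample_fiber_line(cfg), simplify = FALSE)
  set.seed(5); b <- replicate(5, sample_fiber_line(cfg), simplify = FALSE)
  expect_identical(a, b)
})

test_that("centerline is the carrier chord for zero amplitude and deviates by the amplitude otherwise", {
  cfg <- simulation_config()
  set.seed(21)
  for (i in 1:20) {
    sp <- sample_fiber_line(cfg)
    cl <- fiber_centerline(sp, cfg)
    if (nrow(cl) < 10) next
    # signed perpendicular offset of each point from the carrier line
    cx <- (cfg$width - 1) / 2; cy <- (cfg$height - 1) / 2
    vx <- cos(sp$alpha); vy <- sin(sp$alpha)
    off <- (cl[, "col"] - cx) * vx + (cl[, "row"] - cy) * vy - sp$d
    # the sampled polyline may miss the exact sine crest by a fraction of
    # the 0.25 px step
    expect_equal(max(abs(off)), sp$amplitude, tolerance = 1e-3)
    sp0 <- sp; sp0$amplitude <- 0
    cl0 <- fiber_centerline(sp0, cfg)
    off0 <- (cl0[, "col"] - cx) * vx + (cl0[, "row"] - cy) * vy - sp0$d
    expect_lt(max(abs(off0)), 1e-9)
  }
})

test_that("rotating the carrier by pi reflects the zero-amplitude centerline through the centre", {
  cfg <- simulation_config()
  sp <- structure(list(d = 30, alpha = 0.7, amplitude = 0, diameter = 5,
                       gray = 100), class = "fiber_spec")
  sp2 <- sp; sp2$alpha <- sp$alpha + pi
  cl <- fiber_centerline(sp, cfg)
  cl2 <- fiber_centerline(sp2, cfg)
  expect_gt(nrow(cl), 0); expect_gt(nrow(cl2), 0)
  cx <- (cfg$width - 1) / 2; cy <- (cfg$height - 1) / 2
  # reflected points must lie on the alpha + pi carrier line
  refl <- cbind(row = 2 * cy - cl[, "row"], col = 2 * cx - cl[, "col"])
  vx <- cos(sp2$alpha); vy <- sin(sp2$alpha)
  dist_to_line <- (refl[, "col"] - cx) * vx + (refl[, "row"] - cy) * vy -
    sp2$d
  expect_lt(max(abs(dist_to_line)), 1e-9)
})

test_that("a carrier line that misses the canvas yields a flagged empty polyline", {
  cfg <- simulation_config()
  sp <- structure(list(d = 0.99 * sqrt(cfg$height^2 + cfg$width^2),
                       alpha = 0, amplitude = 0, diameter = 5, gray = 100),
                  class = "fiber_spec")
  cl <- fiber_centerline(sp, cfg)
  expect_equal(nrow(cl), 0)
  expect_true(isTRUE(attr(cl, "degenerate")))
  expect_equal(sum(rasterize_fiber(cl, 5, c(32, 32))), 0)
})

test_that("rasterization reproduces the drawn thickness", {
  # horizontal band of diameter 5 on 32 x 32: distance transform peaks at 3
  pts <- cbind(row = rep(15, 121), col = seq(5, 29, by = 0.2))
  m <- rasterize_fiber(pts, 5, c(32, 32))
  expect_equal(max(bf_edt(m)), 3)
  band_rows <- range(which(rowSums(m) > 0))
  expect_equal(diff(band_rows) + 1, 5)
  # diameter 1 reduces to the rasterized centerline itself
  m1 <- rasterize_fiber(pts, 1, c(32, 32))
  expect_equal(sum(m1), length(unique(round(pts[, "col"]))))
  expect_true(all(m1[16, 6:30] == 1))   # 0-based point coords -> row 16
  # dilation is extensive
  expect_gte(sum(m), sum(m1))
})

test_that("composed micrographs satisfy their structural contracts", {
  cfg <- desk_cfg()
  s <- compose_micrograph(cfg, seed = 42)
  expect_s3_class(s, "synthetic_sample")
  expect_equal(dim(s$image), c(64, 64, 3))
  expect_equal(length(s$specs), length(s$per_fiber_masks))
  expect_true(length(s$specs) >= 1 && length(s$specs) <= 5)
  expect_identical(s$mask, {
    u <- Reduce(pmax, s$per_fiber_masks); storage.mode(u) <- "integer"; u
  })
  expect_identical(s, compose_micrograph(cfg, seed = 42))
})

test_that("noise-free fibers carry one exact gray level outside overlaps", {
  cfg <- desk_cfg(pixel_noise_sigma = 0, global_noise_sigma = 0)
  s <- compose_micrograph(cfg, seed = 8)
  overlap <- Reduce(`+`, s$per_fiber_masks) > 1
  k <- length(s$specs)
  for (i in seq_len(k)) {
    own <- s$per_fiber_masks[[i]] == 1 & !overlap
    # painter's order: later fibers may overwrite, but own non-overlap pixels
    # keep the assigned gray
    if (!any(own)) next
    vals <- unique(round(s$image[, , 1][own] * 255))
    expect_equal(vals, s$specs[[i]]$gray)
  }
  grays <- vapply(s$specs, `[[`, numeric(1), "gray")
  expect_equal(anyDuplicated(grays), 0)
})

test_that("dataset generation is seed-reproducible down to the PNG bytes", {
  cfg <- tiny_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_dataset(cfg, 3, seed = 7, dir = d1)
  s2 <- generate_dataset(cfg, 3, seed = 7, dir = d2)
  expect_length(s1, 3)
  expect_identical(s1, s2)
  for (f in list.files(d1, pattern = "png$")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_length(man$samples, 3)
  expect_length(generate_dataset(cfg, 1, seed = 1), 1)
})

test_that("disabling noise and curvature yields exact straight bands", {
  cfg <- simulation_config(height = 48, width = 48,
                           fiber_count_range = c(1, 1),
                           amplitude_frac_range = c(0, 0),
                           pixel_noise_sigma = 0, global_noise_sigma = 0)
  set.seed(33)
  s <- compose_micrograph(cfg)
  # every mask row/column cut perpendicular to the fiber has constant width:
  # check via the EDT maximum matching the analytic band value
  v <- pad_edt_max(s$mask)
  d <- s$specs[[1]]$diameter
  expect_true(2 * v - 1 <= d && d <= 2 * v + 1)
})
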