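test_that("segmentation counts components correctly", {
  expect_equal(segment_from_distance_map(matrix(0, 8, 8))$n_components, 0)
  # two parallel bands two background rows apart
  m <- matrix(0L, 16, 16)
  m[3:5, ] <- 1L; m[9:11, ] <- 1L
  map <- euclidean_distance_transform(m)
  seg <- segment_from_distance_map(map)
  expect_equal(seg$n_components, 2)
  expect_equal(segment_from_distance_map(map,
                                         threshold = max(map))$n_components,
               0)
  # 8-connectivity: a diagonal chain is one component
  d <- matrix(0L, 6, 6); d[cbind(1:5, 1:5)] <- 1L
  expect_equal(segment_from_distance_map(
    euclidean_distance_transform(d))$n_components, 1)
})

test_that("the ridge of a straight band is its centre line", {
  m <- make_band(16, 20, 7, 5)           # diameter-5 band, rows 7..11
  map <- euclidean_distance_transform(m)
  seg <- segment_from_distance_map(map)
  ridge <- extract_ridge(map, (seg$labels == 1) * 1L)
  expect_gt(nrow(ridge), 0)
  vals <- attr(ridge, "values")
  expect_true(all(vals == 3))            # centre-row distance of width 5
  expect_true(all(ridge[, "row"] == 9))
  # ridge is contained in the component
  expect_true(all(m[ridge] == 1))
})

test_that("degenerate components are handled", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  map <- euclidean_distance_transform(m)
  ridge <- extract_ridge(map, m)
  expect_equal(nrow(ridge), 1)
  expect_equal(unname(ridge[1, ]), c(4, 4))
  expect_error(extract_ridge(map, matrix(0L, 7, 7)), "empty component")
})

test_that("diameter estimation follows the calibrated ridge formula", {
  m <- estimate_diameter(rep(3, 20))
  expect_s3_class(m, "fiber_measurement")
  expect_equal(m$diameter_px, 2 * 3 - 0.2)
  expect_false(m$flagged)
  expect_equal(estimate_diameter(rep(3, 20), calibration = 2)$diameter_um,
               2 * (2 * 3 - 0.2))
  # sub-pixel ridges clamp to one pixel and are flagged
  sub <- estimate_diameter(rep(0.5, 5))
  expect_equal(sub$diameter_px, 1)
  expect_true(sub$flagged)
  # crossing filter drops outlier radii before aggregation
  radii <- c(rep(2.5, 30), rep(6, 3))
  expect_lt(estimate_diameter(radii)$diameter_px, 5.2)
  expect_error(estimate_diameter(numeric(0)), "empty ridge")
})

test_that("diameters recover within one pixel on straight isolated fibers", {
  cfg <- straight_cfg(height = 96, width = 96)
  set.seed(17)
  errs <- numeric(0)
  for (k in 1:40) {
    s <- compose_micrograph(cfg)
    map <- euclidean_distance_transform(s$mask)
    meas <- measure_fibers(map)
    expect_equal(meas$n_fibers, 1)
    errs <- c(errs, meas$per_fiber[[1]]$diameter_px -
                s$specs[[1]]$diameter)
  }
  expect_gte(mean(abs(errs) <= 1), 0.95)
})

test_that("thicker drawn fibers never estimate smaller", {
  est <- vapply(3:9, function(d) {
    m <- make_band(24, 30, 8, d)
    map <- euclidean_distance_transform(m)
    measure_fibers(map)$per_fiber[[1]]$diameter_px
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("mean fiber diameter aggregates simple cases", {
  m4 <- estimate_diameter(rep((4 + 0.2) / 2, 5))
  m6 <- estimate_diameter(rep((6 + 0.2) / 2, 5))
  expect_equal(mean_fiber_diameter(list(m4, m6)), 5)
  expect_equal(mean_fiber_diameter(list(m4)), 4)
  expect_equal(mean_fiber_diameter(list(m6, m4)),
               mean_fiber_diameter(list(m4, m6)))
  expect_error(mean_fiber_diameter(list()), "no measurements")
  # two-band map end to end
  m <- matrix(0L, 20, 24); m[3:5, ] <- 1L; m[12:16, ] <- 1L
  meas <- measure_fibers(euclidean_distance_transform(m))
  expect_equal(meas$n_fibers, 2)
  expect_equal(meas$mean_diameter_px,
               mean_fiber_diameter(meas$per_fiber))
})
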