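# a directory of PNG micrograph/mask pairs standing in for real scans
# (synthetic stand-in: no real OFDA images ship with the package)
make_standin_real_dir <- function(n, dir = withr::local_tempdir(
                                    .local_envir = parent.frame())) {
  samples <- generate_dataset(desk_cfg(), n, seed = 99)
  for (i in seq_along(samples)) {
    stem <- file.path(dir, sprintf("real_%03d", i))
    png::writePNG(samples[[i]]$image, paste0(stem, ".png"))
    png::writePNG(samples[[i]]$mask + 0.0, paste0(stem, "_mask.png"))
  }
  dir
}

test_that("default group sizes reproduce the 43/11/43/11 protocol with disjoint digests", {
  dir <- make_standin_real_dir(54)
  groups <- make_groups(desk_cfg(), seed = 2, real_dir = dir)
  expect_equal(vapply(groups[c("g1", "g2", "g3", "g4")], length,
                      integer(1)),
               c(g1 = 43L, g2 = 11L, g3 = 43L, g4 = 11L))
  expect_true(check_protocol_hygiene(groups))
  train <- c(groups$digests$g1, groups$digests$g3)
  test <- c(groups$digests$g2, groups$digests$g4)
  expect_length(intersect(train, test), 0)
  expect_output(print(groups), "43 images")
})

test_that("group membership is deterministic under the seed and real groups optional", {
  g1 <- make_groups(tiny_cfg(), sizes = c(0, 0, 4, 2), seed = 7)
  g2 <- make_groups(tiny_cfg(), sizes = c(0, 0, 4, 2), seed = 7)
  expect_identical(g1$digests, g2$digests)
  expect_length(g1$g1, 0)
  expect_length(g1$g2, 0)
  expect_length(g1$g3, 4)
  expect_error(make_groups(tiny_cfg(), sizes = c(2, 1, 3, 1), seed = 1,
                           real_dir = make_standin_real_dir(2)),
               "requested")
})

test_that("evaluation metrics behave on reference predictors", {
  groups <- make_groups(tiny_cfg(), sizes = c(0, 0, 3, 3), seed = 5)
  labels <- lapply(groups$g4, `[[`, "label")
  perfect <- fibermap:::eval_metrics(labels, labels)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$nrmse, 0)
  zero <- evaluate(function(img) matrix(0, 32, 32), groups$g4)
  expect_equal(zero$mae, mean(vapply(labels, mean, numeric(1))))
  expect_equal(zero$n, 3)
  expect_error(evaluate(function(img) img, list()), "empty test group")
})

test_that("a scaled-down experiment grid covers all cells with finite metrics", {
  samples <- training_pairs(generate_dataset(tiny_cfg(), 8, seed = 6))
  groups <- structure(list(g1 = list(), g2 = list(),
                           g3 = samples[1:6], g4 = samples[7:8],
                           seed = 1L),
                      class = "dataset_groups")
  groups$digests <- lapply(groups[c("g1", "g2", "g3", "g4")],
                           function(g) vapply(g, fibermap:::sample_digest,
                                              character(1)))
  res <- run_experiment_grid(
    groups,
    mconfig_base = model_config(base_channels = 4, depth = 2),
    tconfig = train_config(max_epochs = 2L, augmentation = NULL))
  expect_equal(nrow(res$report), 6)   # 2 architectures x 3 losses, one group
  expect_setequal(unique(res$report$architecture),
                  c("unet", "skeletonnet"))
  expect_setequal(unique(res$report$loss), c("l1", "l2", "smooth_l1"))
  expect_true(all(is.finite(res$report$mae)))
  expect_true(all(res$report$mae >= 0 & res$report$mse >= 0))
  expect_length(res$models, 6)
})
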