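test_that("augmentation applies geometric transforms to image and label alike", {
  s <- compose_micrograph(tiny_cfg(), seed = 1)
  lab <- make_label(s)
  id_spec <- augmentation_spec(transforms = character(0))
  out <- augment(s$image, lab, id_spec)
  expect_identical(out$image, s$image)
  expect_identical(out$label, lab)
  # horizontal flip is an involution
  hf <- augmentation_spec("horizontal_flip", prob = 1)
  once <- augment(s$image, lab, hf)
  twice <- augment(once$image, once$label, hf)
  expect_equal(twice$image, s$image)
  expect_equal(twice$label, lab)
  # flipping commutes with the distance transform (exact)
  flipped_mask <- s$mask[, rev(seq_len(ncol(s$mask)))]
  expect_equal(euclidean_distance_transform(flipped_mask),
               euclidean_distance_transform(s$mask)[, rev(seq_len(ncol(s$mask)))])
  # and so does rotation by 90 degrees
  rot_mask <- t(s$mask[rev(seq_len(nrow(s$mask))), ])
  expect_equal(euclidean_distance_transform(rot_mask),
               t(euclidean_distance_transform(s$mask)[rev(seq_len(nrow(s$mask))), ]))
  expect_error(augmentation_spec("solarize"), "unknown transform")
})

test_that("photometric transforms leave the label untouched", {
  s <- compose_micrograph(tiny_cfg(), seed = 2)
  lab <- make_label(s)
  ph <- augmentation_spec(c("gaussian_blur", "posterization",
                            "autocontrast"), prob = 1)
  set.seed(1)
  out <- augment(s$image, lab, ph)
  expect_identical(out$label, lab)
  expect_false(identical(out$image, s$image))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("augmentation accounting follows initial size times 2^T", {
  expect_equal(effective_dataset_size(43, 1), 86)
  expect_equal(effective_dataset_size(43, 2), 172)
  expect_equal(effective_dataset_size(43, 3), 344)
})

test_that("fusing training sets concatenates and shuffles deterministically", {
  real <- as.list(1:43)
  synth <- as.list(101:143)
  fused <- fuse_training_sets(real, synth, seed = 5)
  expect_length(fused, 86)
  expect_setequal(unlist(fused), c(1:43, 101:143))
  expect_identical(fused, fuse_training_sets(real, synth, seed = 5))
  only <- fuse_training_sets(list(), synth, seed = 1)
  expect_setequal(unlist(only), unlist(synth))
  expect_length(only, length(synth))
  expect_error(fuse_training_sets(list(), list()), "empty")
})

test_that("training respects epoch caps, early stopping and determinism", {
  tset <- training_pairs(generate_dataset(tiny_cfg(), 5, seed = 3))
  mc <- model_config("unet", base_channels = 4, depth = 2)
  one <- train_model(tset, train_config(max_epochs = 1L, seed = 2,
                                        augmentation = NULL), mc)
  expect_equal(nrow(one$history), 1)
  fit <- train_model(tset, train_config(max_epochs = 40L,
                                        early_stop_patience = 3L, seed = 2,
                                        augmentation = NULL), mc)
  expect_lte(nrow(fit$history), fit$best_epoch + 3)
  expect_equal(min(fit$history$val_loss),
               fit$history$val_loss[fit$best_epoch])
  again <- train_model(tset, train_config(max_epochs = 40L,
                                          early_stop_patience = 3L, seed = 2,
                                          augmentation = NULL), mc)
  expect_identical(fit$history, again$history)
  expect_identical(fit$model$params, again$model$params)
  # learning rate drops once after the configured epoch
  expect_equal(unique(fit$history$lr[fit$history$epoch <= 10]), 1e-3)
  if (nrow(fit$history) > 10)
    expect_equal(unique(fit$history$lr[fit$history$epoch > 10]), 1e-4)
})

test_that("the distreg front end fits, predicts and reports", {
  samples <- generate_dataset(tiny_cfg(), 6, seed = 4)
  fit <- distreg(samples, architecture = "unet", loss = "l1",
                 base_channels = 4, depth = 2,
                 control = train_config(max_epochs = 3L,
                                        augmentation = NULL))
  expect_s3_class(fit, "distreg")
  expect_output(print(fit), "unet, l1 loss")
  expect_output(print(summary(fit)), "parameters")
  map <- predict(fit, samples[[1]])
  expect_equal(dim(map), c(32, 32))
  expect_true(all(map >= 0))
  map_px <- predict(fit, samples[[1]], units = "pixels")
  expect_equal(map_px, map * label_scale(9))
  res <- residuals(fit)
  expect_length(res, 6)
  expect_equal(dim(res[[1]]), c(32, 32))
  expect_gt(length(coef(fit)), 1000)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
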