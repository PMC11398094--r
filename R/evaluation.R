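#' Build the four-group evaluation protocol
#'
#' Groups G1/G2 are real training/testing micrographs (read from
#' `real_dir`, which must contain `*.png` images with matching
#' `*_mask.png` masks); groups G3/G4 are synthetic training/testing
#' micrographs generated fresh from the simulator. Training groups are used
#' for fitting and cross-validation only; test groups must never be touched
#' before evaluation, which [check_protocol_hygiene()] verifies by content
#' digest.
#'
#' @param synthetic_config A [simulation_config()] for G3/G4.
#' @param sizes Named or positional sizes `c(g1, g2, g3, g4)`
#'   (default `c(43, 11, 43, 11)`).
#' @param seed Integer seed; membership is deterministic under it.
#' @param real_dir Optional directory of real micrographs; `NULL` leaves
#'   G1/G2 empty (synthetic-only protocol).
#' @param normalize,max_diameter Label space passed to [make_label()].
#' @return An object of class `dataset_groups`: lists `g1`..`g4` of samples
#'   (`image`, `label`, `mask`) plus per-group content digests.
#' @export
make_groups <- function(synthetic_config = simulation_config(),
                        sizes = c(g1 = 43L, g2 = 11L, g3 = 43L, g4 = 11L),
                        seed = 1L, real_dir = NULL,
                        normalize = TRUE, max_diameter = 9) {
  stopifnot(length(sizes) == 4)
  sizes <- as.integer(sizes)
  set.seed(seed)
  to_sample <- function(s) list(image = s$image, mask = s$mask,
                                label = make_label(s, normalize,
                                                   max_diameter))
  g3 <- lapply(generate_dataset(synthetic_config, sizes[3]), to_sample)
  g4 <- lapply(generate_dataset(synthetic_config, sizes[4]), to_sample)
  if (is.null(real_dir)) {
    g1 <- list(); g2 <- list()
    if (sizes[1] > 0 || sizes[2] > 0) {
      sizes[1] <- 0L; sizes[2] <- 0L
    }
  } else {
    real <- load_real_samples(real_dir, normalize, max_diameter)
    if (length(real) < sizes[1] + sizes[2])
      stop(sprintf("real_dir holds %d labeled images; %d requested",
                   length(real), sizes[1] + sizes[2]))
    perm <- sample.int(length(real))
    g1 <- real[perm[seq_len(sizes[1])]]
    g2 <- real[perm[sizes[1] + seq_len(sizes[2])]]
  }
  groups <- structure(list(g1 = g1, g2 = g2, g3 = g3, g4 = g4,
                           seed = seed),
                      class = "dataset_groups")
  groups$digests <- lapply(groups[c("g1", "g2", "g3", "g4")],
                           function(g) vapply(g, sample_digest,
                                              character(1)))
  check_protocol_hygiene(groups)
  groups
}

load_real_samples <- function(dir, normalize, max_diameter) {
  imgs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  imgs <- imgs[!grepl("_mask\\.png$", imgs)]
  out <- list()
  for (f in imgs) {
    mf <- sub("\\.png$", "_mask.png", f)
    if (!file.exists(mf)) next   # unlabeled real images cannot be used
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    mask <- (png::readPNG(mf) > 0.5) * 1L
    if (length(dim(mask)) == 3) mask <- mask[, , 1]
    storage.mode(mask) <- "integer"
    out[[length(out) + 1L]] <- list(
      image = img[, , 1:3, drop = FALSE], mask = mask,
      label = pmin(euclidean_distance_transform(mask) /
                     (if (normalize) label_scale(max_diameter) else 1),
                   if (normalize) 1 else Inf))
  }
  out
}

sample_digest <- function(sample) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(sample$image, NULL, xdr = TRUE), f)
  unname(tools::md5sum(f))
}

#' Verify train/test disjointness by content digest
#'
#' @param groups A `dataset_groups` object.
#' @return `TRUE` invisibly; errors if any test image also appears in a
#'   training group.
#' @export
check_protocol_hygiene <- function(groups) {
  stopifnot(inherits(groups, "dataset_groups"))
  train <- c(groups$digests$g1, groups$digests$g3)
  test <- c(groups$digests$g2, groups$digests$g4)
  overlap <- intersect(train, test)
  if (length(overlap))
    stop(sprintf("%d test image(s) leak into the training groups",
                 length(overlap)))
  invisible(TRUE)
}

#' @export
print.dataset_groups <- function(x, ...) {
  cat("Evaluation protocol groups:\n")
  cat(sprintf("  G1 real training:      %3d images\n", length(x$g1)))
  cat(sprintf("  G2 real testing:       %3d images\n", length(x$g2)))
  cat(sprintf("  G3 synthetic training: %3d images\n", length(x$g3)))
  cat(sprintf("  G4 synthetic testing:  %3d images\n", length(x$g4)))
  invisible(x)
}

eval_metrics <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions), length(labels) > 0)
  data.frame(
    n = length(labels),
    mae = mae(labels, predictions),
    mse = mse(labels, predictions),
    nrmse = nrmse(labels, predictions)
  )
}

#' Evaluate a model on a test group
#'
#' Reports MAE, MSE (the training criteria applied as metrics, averaged per
#' image) and NRMSE over a held-out group, in the map space the model was
#' trained in.
#'
#' @param model A fitted [distreg], a `fibermap_model`, or a function
#'   mapping an image to a map (useful for baselines).
#' @param samples Nonempty list of samples with `image` and `label`.
#' @return A one-row data.frame: `n`, `mae`, `mse`, `nrmse`.
#' @export
evaluate <- function(model, samples) {
  if (length(samples) == 0) stop("empty test group")
  predict1 <- if (is.function(model)) model
              else function(img) predict_distance_map(model, img)
  labels <- lapply(samples, `[[`, "label")
  preds <- lapply(samples, function(s) predict1(s$image))
  eval_metrics(labels, preds)
}

#' Run the architecture x loss experiment grid
#'
#' Trains one model per (architecture, loss) cell on the fused training
#' groups (G1 + G3, shuffled under the seed) and evaluates every cell on
#' each nonempty test group, mirroring the protocol's report tables.
#'
#' @param groups A [make_groups()] result.
#' @param archs,losses Character vectors of cells to run.
#' @param mconfig_base A [model_config()] whose `base_channels`/`depth` are
#'   reused for every architecture.
#' @param tconfig A [train_config()]; its `loss` field is set per cell.
#' @param verbose Print progress.
#' @return List with `report` (data.frame: architecture, loss, group, n,
#'   mae, mse, nrmse) and `models` (named list of fitted models).
#' @export
run_experiment_grid <- function(groups,
                                archs = c("unet", "skeletonnet"),
                                losses = c("l1", "l2", "smooth_l1"),
                                mconfig_base = model_config(),
                                tconfig = train_config(),
                                verbose = FALSE) {
  stopifnot(inherits(groups, "dataset_groups"))
  train_set <- fuse_training_sets(groups$g1, groups$g3, seed = groups$seed)
  tests <- Filter(function(g) length(groups[[g]]) > 0, c("g2", "g4"))
  report <- NULL
  models <- list()
  for (arch in archs) for (lo in losses) {
    if (verbose) message(sprintf("training %s / %s", arch, lo))
    tc <- tconfig; tc$loss <- lo
    mc <- model_config(arch, in_channels = 3L,
                       base_channels = mconfig_base$base_channels,
                       depth = mconfig_base$depth)
    fit <- train_model(train_set, tc, mc, verbose = verbose)
    models[[paste(arch, lo, sep = "_")]] <- fit$model
    for (g in tests) {
      row <- evaluate(fit$model, groups[[g]])
      report <- rbind(report,
                      cbind(data.frame(architecture = arch, loss = lo,
                                       group = g), row))
    }
  }
  list(report = report, models = models)
}
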