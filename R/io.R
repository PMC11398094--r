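#' Read and write distance maps as 32-bit float TIFF
#'
#' Float TIFF storage holds values in `[0, 1]`, so maps with larger values
#' (raw pixel-unit maps) are divided by the next power of two above their
#' maximum -- exact in floating point -- and the scale is recorded in a
#' `<path>.json` sidecar read back on load. Values are stored in single
#' precision.
#'
#' @param map Numeric matrix of non-negative values.
#' @param path Output path (`.tiff`).
#' @return `read_distance_map` returns the matrix; `write_distance_map` the
#'   path, invisibly.
#' @export
write_distance_map <- function(map, path) {
  stopifnot(is.matrix(map), all(map >= 0))
  mx <- max(map)
  s <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  suppressWarnings(tiff::writeTIFF(map / s, path, bits.per.sample = 32L))
  sidecar <- paste0(path, ".json")
  if (s > 1) {
    jsonlite::write_json(list(scale = s), sidecar, auto_unbox = TRUE,
                         digits = NA)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
  invisible(path)
}

#' @rdname write_distance_map
#' @export
read_distance_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    m <- m * jsonlite::read_json(sidecar)$scale
  m
}

#' Read a micrograph PNG as an RGB array
#'
#' @param path PNG file.
#' @return `H x W x 3` array in `[0, 1]` (grayscale files are replicated
#'   across channels).
#' @export
read_micrograph <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Load a simulation configuration from YAML
#'
#' The YAML fields mirror [simulation_config()] arguments one-for-one;
#' missing fields keep their defaults.
#'
#' @param path YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

#' Save / load a fitted model checkpoint
#'
#' Checkpoints are plain lists (weights + configuration + training seed)
#' written with [saveRDS()]; `load_checkpoint` restores an object usable
#' with [predict_distance_map()] and [predict.distreg()].
#'
#' @param fit A [distreg] fit or `fibermap_model`.
#' @param path Output `.rds` path.
#' @export
save_checkpoint <- function(fit, path) {
  if (inherits(fit, "distreg")) fit$data <- NULL   # weights, not data
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a run manifest
#'
#' Every command-line run records its command, configuration snapshot, seed,
#' input/output paths and package version, so reruns are reproducible.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param config Configuration list (serialized as-is).
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of paths.
#' @export
write_run_manifest <- function(path, command, config = NULL, seed = NULL,
                               inputs = character(), outputs = character()) {
  digest1 <- function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = as.list(stats::setNames(vapply(inputs, digest1, character(1)),
                                     inputs)),
    outputs = as.character(outputs),
    package_version = as.character(utils::packageVersion("fibermap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
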