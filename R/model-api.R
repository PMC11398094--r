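#' Model configuration for the distance-map regressors
#'
#' @param architecture `"unet"` (plain symmetric encoder--decoder with skip
#'   connections) or `"skeletonnet"` (coordinate channels, residual squeezed
#'   blocks, csSE and four fused side outputs).
#' @param in_channels Input channels (3 for RGB micrographs).
#' @param base_channels First-stage feature width (default 64, as in the
#'   original U-Net; reduce for desk-scale experiments).
#' @param depth Number of encoder stages (default 4).
#' @return An object of class `model_config`.
#' @export
model_config <- function(architecture = c("unet", "skeletonnet"),
                         in_channels = 3L, base_channels = 64L, depth = 4L) {
  architecture <- match.arg(architecture)
  stopifnot(base_channels >= 4, depth >= 2, in_channels >= 1)
  structure(list(architecture = architecture,
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth)),
            class = "model_config")
}

#' Build an initialized (untrained) regression model
#'
#' Weights are He-initialized from the current RNG state; set a seed first
#' for reproducible initialization.
#'
#' @param config A [model_config()].
#' @return An object of class `fibermap_model` (list of `params` + config).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  params <- switch(config$architecture,
    unet = unet_init(config$in_channels, config$base_channels, config$depth),
    skeletonnet = sknet_init(config$in_channels, config$base_channels,
                             config$depth))
  structure(list(params = params, config = config), class = "fibermap_model")
}

model_forward <- function(model, x, with_tape = TRUE, ...) {
  switch(model$config$architecture,
    unet = unet_forward(model$params, x, with_tape = with_tape),
    skeletonnet = sknet_forward(model$params, x, with_tape = with_tape, ...))
}

model_backward <- function(model, tape, gy) {
  switch(model$config$architecture,
    unet = unet_backward(model$params, tape, gy),
    skeletonnet = sknet_backward(model$params, tape, gy))
}

check_input_size <- function(model, d) {
  if (length(d) != 3 || d[3] != model$config$in_channels)
    stop(sprintf("expected a H x W x %d input image",
                 model$config$in_channels))
  s <- d[1:2]
  for (i in seq_len(model$config$depth)) {
    s <- s %/% 2L
    if (any(s < 2))
      stop(sprintf(
        "input %d x %d too small for depth %d (stage %d would be %d x %d)",
        d[1], d[2], model$config$depth, i, s[1], s[2]))
  }
  invisible(TRUE)
}

#' Predict a distance map from a micrograph
#'
#' Runs the forward pass in evaluation mode; the linear output is clamped at
#' 0 so the result is a valid (non-negative) distance map.
#'
#' @param model A `fibermap_model` or fitted [distreg] object.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return `H x W` numeric matrix, the predicted map in the space the model
#'   was trained in (normalized by default).
#' @export
predict_distance_map <- function(model, image) {
  if (inherits(model, "distreg")) model <- model$model
  stopifnot(inherits(model, "fibermap_model"))
  image <- as_cube(image)
  check_input_size(model, dim(image))
  y <- model_forward(model, image, with_tape = FALSE)$y
  if (any(!is.finite(y))) stop("model produced non-finite values")
  pmax(y, 0)
}
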