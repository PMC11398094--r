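#' Fit a distance-map regression model to fiber micrographs
#'
#' The front door of the package: trains a convolutional encoder--decoder
#' that maps an RGB micrograph to its Euclidean distance map, from which
#' individual fibers can be segmented and their diameters measured (see
#' [measure_fibers()]). Labels are computed from ground-truth masks when `x`
#' is a list of simulated samples, or supplied directly via `y`.
#'
#' @param x List of training inputs: either `synthetic_sample` objects from
#'   [compose_micrograph()]/[generate_dataset()] (labels derived
#'   automatically) or `H x W x 3` arrays (then `y` is required).
#' @param y Optional list of `H x W` distance-map labels matching `x`.
#' @param architecture `"unet"` or `"skeletonnet"`.
#' @param loss `"smooth_l1"`, `"l1"` or `"l2"`.
#' @param base_channels,depth Network size (see [model_config()]); the
#'   defaults here are desk-scale, not the full-width network.
#' @param normalize Train on labels rescaled to `[0, 1]` by [label_scale()]
#'   (default `TRUE`).
#' @param max_diameter Diameter bound used for the label scale.
#' @param control A [train_config()]; its `loss` is overridden by the `loss`
#'   argument.
#' @param keep_data Store the training samples in the fit (enables
#'   `residuals()` without new data).
#' @param verbose Print per-epoch progress.
#' @return An object of class `distreg` with methods `print`, `summary`,
#'   `predict`, `residuals`, `plot` and `coef`.
#' @export
#' @examples
#' \donttest{
#' cfg <- simulation_config(height = 32, width = 32,
#'                          fiber_count_range = c(1, 3))
#' samples <- generate_dataset(cfg, 6, seed = 1)
#' fit <- distreg(samples, base_channels = 4, depth = 2,
#'                control = train_config(max_epochs = 2))
#' print(fit)
#' map <- predict(fit, samples[[1]])
#' }
distreg <- function(x, y = NULL,
                    architecture = c("unet", "skeletonnet"),
                    loss = c("smooth_l1", "l1", "l2"),
                    base_channels = 16L, depth = 3L,
                    normalize = TRUE, max_diameter = 9,
                    control = train_config(), keep_data = TRUE,
                    verbose = FALSE) {
  architecture <- match.arg(architecture)
  loss <- match.arg(loss)
  cl <- match.call()
  samples <- as_training_set(x, y, normalize, max_diameter)
  control$loss <- loss
  mconfig <- model_config(architecture, in_channels = 3L,
                          base_channels = base_channels, depth = depth)
  fit <- train_model(samples, control, mconfig, verbose = verbose)
  structure(list(
    model = fit$model, history = fit$history, best_epoch = fit$best_epoch,
    architecture = architecture, loss = loss, normalize = normalize,
    scale = label_scale(max_diameter), control = control,
    n_train = length(samples),
    data = if (keep_data) samples else NULL,
    call = cl
  ), class = "distreg")
}

as_training_set <- function(x, y, normalize, max_diameter) {
  if (length(x) == 0) stop("empty training set")
  if (inherits(x, "synthetic_sample")) x <- list(x)
  lapply(seq_along(x), function(i) {
    xi <- x[[i]]
    if (inherits(xi, "synthetic_sample")) {
      list(image = xi$image,
           label = if (is.null(y)) make_label(xi, normalize, max_diameter)
                   else y[[i]])
    } else if (is.list(xi) && !is.null(xi$image) && !is.null(xi$label)) {
      xi[c("image", "label")]
    } else {
      if (is.null(y)) stop("supply labels 'y' for raw image inputs")
      list(image = xi, label = y[[i]])
    }
  })
}

#' @export
print.distreg <- function(x, ...) {
  cat(sprintf("Distance-map regression (%s, %s loss)\n",
              x$architecture, x$loss))
  cat(sprintf("  trained on %d images for %d epochs (best epoch %d)\n",
              x$n_train, nrow(x$history), x$best_epoch))
  cat(sprintf("  best validation loss: %.5f\n",
              min(x$history$val_loss)))
  cat(sprintf("  label space: %s\n",
              if (x$normalize) sprintf("normalized (scale %.1f px)", x$scale)
              else "raw pixels"))
  invisible(x)
}

#' @export
summary.distreg <- function(object, ...) {
  structure(list(
    fit = object,
    n_params = count_params(object$model$params),
    final = tail(object$history, 1L),
    best_val = min(object$history$val_loss)
  ), class = "summary.distreg")
}

#' @export
print.summary.distreg <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  parameters: %s\n", format(x$n_params, big.mark = ",")))
  cat(sprintf("  final epoch %d: train %.5f, val %.5f (lr %.1e)\n",
              x$final$epoch, x$final$train_loss, x$final$val_loss,
              x$final$lr))
  invisible(x)
}

#' @param object A fitted `distreg`.
#' @param newdata A single image/sample or a list of them.
#' @param units `"trained"` returns maps in the space the model was trained
#'   in; `"pixels"` rescales normalized maps back to pixel units.
#' @rdname distreg
#' @export
predict.distreg <- function(object, newdata,
                            units = c("trained", "pixels"), ...) {
  units <- match.arg(units)
  single <- inherits(newdata, "synthetic_sample") ||
    (is.array(newdata) && length(dim(newdata)) == 3)
  items <- if (single) list(newdata) else newdata
  maps <- lapply(items, function(it) {
    img <- if (inherits(it, "synthetic_sample")) it$image
           else if (is.list(it) && !is.null(it$image)) it$image else it
    m <- predict_distance_map(object$model, img)
    if (units == "pixels" && object$normalize) m <- m * object$scale
    m
  })
  if (single) maps[[1]] else maps
}

#' @export
residuals.distreg <- function(object, newdata = NULL, newlabels = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data))
      stop("fit stored no data; pass newdata (and labels)")
    newdata <- object$data
  }
  set <- as_training_set(newdata, newlabels, object$normalize,
                         2 * object$scale - 1)
  lapply(set, function(s)
    s$label - predict_distance_map(object$model, s$image))
}

#' @export
coef.distreg <- function(object, ...) {
  leaves <- param_leaves(object$model$params)
  unlist(leaves)
}

#' @export
plot.distreg <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = sprintf("%s loss", x$loss), ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "gray40")
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
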