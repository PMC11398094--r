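#' Training losses and evaluation metrics for distance maps
#'
#' The three training criteria -- L1 (mean absolute difference), L2 (mean
#' squared difference) and smooth-L1 (quadratic within one pixel unit of
#' error, linear beyond) -- each reduce by the mean over all `n * p` pixels;
#' dataset-level values are the mean of per-image values. `mae()`/`mse()`
#' are the same formulas reported as evaluation metrics; `nrmse()` divides
#' the root mean squared error by the range of the ground-truth map.
#'
#' @param target,prediction Numeric matrices of equal shape, or lists of
#'   such matrices (dataset-level: the mean of per-image values).
#' @return A scalar.
#' @name losses
NULL

pairwise_reduce <- function(target, prediction, f) {
  if (is.list(target) || is.list(prediction)) {
    stopifnot(is.list(target), is.list(prediction),
              length(target) == length(prediction))
    if (length(target) == 0) stop("empty set of maps")
    return(mean(mapply(function(a, b) pairwise_reduce(a, b, f),
                       target, prediction)))
  }
  if (!identical(dim(target), dim(prediction)))
    stop("target and prediction shapes differ")
  f(target, prediction)
}

#' @rdname losses
#' @export
l1_loss <- function(target, prediction)
  pairwise_reduce(target, prediction, function(a, b) mean(abs(a - b)))

#' @rdname losses
#' @export
l2_loss <- function(target, prediction)
  pairwise_reduce(target, prediction, function(a, b) mean((a - b)^2))

#' @rdname losses
#' @export
smooth_l1_loss <- function(target, prediction)
  pairwise_reduce(target, prediction, function(a, b) {
    x <- abs(a - b)
    mean(ifelse(x < 1, 0.5 * x^2, x - 0.5))
  })

#' @rdname losses
#' @export
mae <- l1_loss

#' @rdname losses
#' @export
mse <- l2_loss

nrmse_single <- function(a, b) {
  rng <- max(a) - min(a)
  if (rng == 0) stop("target has zero range; NRMSE undefined")
  sqrt(mean((a - b)^2)) / rng
}

#' @rdname losses
#' @export
nrmse <- function(target, prediction)
  pairwise_reduce(target, prediction, nrmse_single)

#' Resolve a loss by name
#'
#' @param kind One of `"l1"`, `"l2"`, `"smooth_l1"`.
#' @return List with `fn(target, prediction)` and
#'   `grad(target, prediction)` (gradient w.r.t. the prediction, including
#'   the `1/(n*p)` mean reduction).
#' @export
loss_fn <- function(kind = c("smooth_l1", "l1", "l2")) {
  kind <- match.arg(kind)
  np <- function(a) length(a)
  switch(kind,
    l1 = list(kind = kind, fn = l1_loss,
              grad = function(t, p) sign(p - t) / np(t)),
    l2 = list(kind = kind, fn = l2_loss,
              grad = function(t, p) 2 * (p - t) / np(t)),
    smooth_l1 = list(kind = kind, fn = smooth_l1_loss,
                     grad = function(t, p) pmin(pmax(p - t, -1), 1) / np(t))
  )
}
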