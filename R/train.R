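#' Training configuration
#'
#' Defaults follow the study conditions: Adam optimizer, batch size 4,
#' initial learning rate 1e-3 reduced (x0.1) after 10 epochs, at most 500
#' epochs, early stopping when the validation loss has not improved for 15
#' epochs.
#'
#' @param loss `"l1"`, `"l2"` or `"smooth_l1"`.
#' @param batch_size Gradient-accumulation batch size (>= 1).
#' @param initial_lr Initial Adam learning rate.
#' @param lr_drop_epoch Epoch after which the rate is multiplied by
#'   `lr_factor` (once).
#' @param lr_factor Learning-rate drop factor.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param validation_fraction Held-out fraction of the training set used for
#'   early stopping (a single training sample validates on itself).
#' @param augmentation An [augmentation_spec()], or `NULL` for none.
#' @param seed Integer seed controlling shuffling, augmentation draws and
#'   weight initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = c("smooth_l1", "l1", "l2"),
                         batch_size = 4L, initial_lr = 1e-3,
                         lr_drop_epoch = 10L, lr_factor = 0.1,
                         max_epochs = 500L, early_stop_patience = 15L,
                         validation_fraction = 0.2,
                         augmentation = augmentation_spec(),
                         seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1, initial_lr > 0, max_epochs >= 1,
            early_stop_patience >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(loss = loss, batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_factor = lr_factor, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(grads) {
  list(m = tree_map(function(x) x * 0, grads),
       v = tree_map(function(x) x * 0, grads), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# forward + loss + backward for one (image, label) pair
grad_sample <- function(model, image, label, lf) {
  fw <- model_forward(model, image, with_tape = TRUE)
  loss <- lf$fn(label, fw$y)
  gy <- lf$grad(label, fw$y)
  grads <- model_backward(model, fw$tape, gy)
  list(loss = loss, grads = grads)
}

#' Train a distance-map regression model
#'
#' Minimizes the chosen loss with Adam over the training split, evaluating
#' the validation split after every epoch; keeps the weights of the best
#' validation epoch and stops early when patience is exhausted. All
#' randomness (split, shuffling, augmentation, initialization) flows from
#' `config$seed`, so training is fully deterministic.
#'
#' @param train_set List of samples, each a list with `image`
#'   (`H x W x 3` array) and `label` (`H x W` matrix).
#' @param config A [train_config()].
#' @param mconfig A [model_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (a `fibermap_model` carrying the best weights),
#'   `history` (data.frame: epoch, train_loss, val_loss, lr) and
#'   `best_epoch`.
#' @export
train_model <- function(train_set, config = train_config(),
                        mconfig = model_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"),
            inherits(mconfig, "model_config"), length(train_set) >= 1)
  set.seed(config$seed)
  model <- build_model(mconfig)
  check_input_size(model, dim(as_cube(train_set[[1]]$image)))
  lf <- loss_fn(config$loss)

  n <- length(train_set)
  if (n == 1L) {
    tr_idx <- 1L
    va_idx <- 1L   # degenerate single-sample case: validate on itself
  } else {
    n_val <- max(1L, floor(config$validation_fraction * n))
    va_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), va_idx)
  }

  adam <- NULL
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$initial_lr *
      if (epoch > config$lr_drop_epoch) config$lr_factor else 1
    order <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(order), by = config$batch_size)) {
      idx <- order[start:min(start + config$batch_size - 1, length(order))]
      acc <- NULL; bl <- 0
      for (s in idx) {
        smp <- train_set[[s]]
        if (!is.null(config$augmentation)) {
          a <- augment(smp$image, smp$label, config$augmentation)
          smp <- list(image = a$image, label = a$label)
        }
        gs <- grad_sample(model, smp$image, smp$label, lf)
        bl <- bl + gs$loss
        acc <- if (is.null(acc)) gs$grads
               else tree_map2(`+`, acc, gs$grads)
      }
      acc <- tree_map(function(g) g / length(idx), acc)
      bl <- bl / length(idx)
      if (!is.finite(bl)) stop("training diverged (non-finite loss)")
      if (is.null(adam)) adam <- adam_init(acc)
      st <- adam_step(model$params, acc, adam, lr)
      model$params <- st$params
      adam <- st$state
      ep_loss <- ep_loss + bl; nb <- nb + 1
    }
    val <- mean(vapply(va_idx, function(s) {
      yhat <- model_forward(model, train_set[[s]]$image,
                            with_tape = FALSE)$y
      lf$fn(train_set[[s]]$label, yhat)
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = val, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / nb, val))
    if (val < best$loss)
      best <- list(loss = val, params = model$params, epoch = epoch)
    if (epoch - best$epoch >= config$early_stop_patience) break
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch)
}
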