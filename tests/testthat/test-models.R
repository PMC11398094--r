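test_that("both architectures honour the shape contract, including odd sizes", {
  set.seed(1)
  for (arch in c("unet", "skeletonnet")) {
    m <- build_model(model_config(arch, base_channels = 4, depth = 2))
    for (hw in list(c(24, 24), c(21, 27))) {
      x <- array(runif(prod(hw) * 3), c(hw, 3))
      y <- predict_distance_map(m, x)
      expect_true(is.matrix(y))
      expect_equal(dim(y), hw)
      expect_true(all(is.finite(y)))
      expect_true(all(y >= 0))
    }
    expect_error(predict_distance_map(m, array(runif(24 * 24 * 2),
                                               c(24, 24, 2))), "H x W x 3")
    expect_error(predict_distance_map(m, array(runif(4 * 4 * 3),
                                               c(4, 4, 3))), "too small")
  }
})

test_that("forward passes are deterministic for fixed weights", {
  set.seed(2)
  m <- build_model(model_config("unet", base_channels = 4, depth = 2))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict_distance_map(m, x), predict_distance_map(m, x))
})

test_that("parameter count strictly increases with base channels", {
  count_for <- function(arch, base) {
    set.seed(1)
    fibermap:::count_params(build_model(model_config(arch,
      base_channels = base, depth = 2))$params)
  }
  for (arch in c("unet", "skeletonnet"))
    expect_gt(count_for(arch, 16), count_for(arch, 8))
})

test_that("skeletonnet sees 5 input channels and emits 4 fused side outputs", {
  set.seed(3)
  mc <- model_config("skeletonnet", base_channels = 4, depth = 4)
  m <- build_model(mc)
  # first encoder conv consumes image + 2 coordinate channels
  expect_equal(ncol(m$params$enc[[1]]$c1$W), 5 * 9)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- fibermap:::sknet_forward(m$params, x, with_tape = FALSE,
                                 return_sides = TRUE)
  expect_length(fw$sides, 4)
  for (s in fw$sides) expect_equal(dim(s), c(32, 32))
  # fusion layer takes exactly the four side maps
  expect_equal(ncol(m$params$fuse$W), 4)
})

test_that("coordinate channels break flip equivariance for skeletonnet but not the interior of unet", {
  set.seed(4)
  # translation by a full pooling period, deep in the interior where the
  # zero-padding rims of the convolution stack cannot reach
  x <- array(0, c(56, 56, 3))
  x[25:28, 25:32, ] <- runif(4 * 8 * 3)
  x_shift <- array(0, c(56, 56, 3))
  x_shift[29:32, 25:32, ] <- x[25:28, 25:32, ]
  mu <- build_model(model_config("unet", base_channels = 4, depth = 2))
  yu <- predict_distance_map(mu, x)
  yu_s <- predict_distance_map(mu, x_shift)
  expect_equal(yu_s[29:32, 25:32], yu[25:28, 25:32], tolerance = 1e-8)
  ms <- build_model(model_config("skeletonnet", base_channels = 4,
                                 depth = 2))
  ys <- predict_distance_map(ms, x)
  ys_s <- predict_distance_map(ms, x_shift)
  expect_gt(max(abs(ys_s[29:32, 25:32] - ys[25:28, 25:32])), 1e-6)
})

test_that("analytic gradients match finite differences for both architectures", {
  gradcheck <- function(arch) {
    set.seed(3)
    model <- build_model(model_config(arch, base_channels = 4, depth = 2))
    H <- 9; W <- 10
    x <- array(runif(H * W * 3), c(H, W, 3))
    R <- matrix(rnorm(H * W), H, W)      # linear probe: loss = sum(y * R)
    fw <- fibermap:::model_forward(model, x, with_tape = TRUE)
    grads <- fibermap:::model_backward(model, fw$tape, R)
    loss_at <- function(params) {
      m2 <- model; m2$params <- params
      sum(fibermap:::model_forward(m2, x, with_tape = FALSE)$y * R)
    }
    leaves_g <- fibermap:::param_leaves(grads)
    set.seed(99)
    probes <- sample(names(leaves_g), 15)
    bump <- function(params, path, el, delta) {
      keys <- strsplit(sub("^/", "", path), "/")[[1]]
      rec <- function(node, keys) {
        k <- keys[1]
        kk <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
        if (length(keys) == 1) node[[kk]][el] <- node[[kk]][el] + delta
        else node[[kk]] <- rec(node[[kk]], keys[-1])
        node
      }
      rec(params, keys)
    }
    eps <- 1e-6
    for (pn in probes) {
      el <- sample(length(leaves_g[[pn]]), 1)
      num <- (loss_at(bump(model$params, pn, el, eps)) -
                loss_at(bump(model$params, pn, el, -eps))) / (2 * eps)
      ana <- leaves_g[[pn]][el]
      expect_equal(ana, num, tolerance = 1e-4,
                   label = sprintf("%s grad at %s[%d]", arch, pn, el))
    }
  }
  gradcheck("unet")
  gradcheck("skeletonnet")
})
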