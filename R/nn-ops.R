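# Layer primitives over the compiled kernels, each as a fwd/bwd pair working
# on H x W x C arrays. Caches hold exactly what the backward pass needs.

as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

conv_param <- function(cin, cout, k) {
  fan_in <- cin * k * k
  list(W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
       b = numeric(cout), k = k)
}

upconv_param <- function(cin, cout) {
  fan_in <- cin * 4
  list(W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
       b = numeric(cout))
}

dense_param <- function(nin, nout) {
  list(W = matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

conv_fwd <- function(x, p) {
  x <- as_cube(x)
  list(y = conv2d_fwd_cpp(x, p$W, p$b, p$k), x = x)
}

conv_bwd <- function(cache, p, g) {
  r <- conv2d_bwd_cpp(cache$x, p$W, p$k, as_cube(g))
  list(gx = r$gx, gp = list(W = r$gW, b = as.numeric(r$gb)))
}

# two (conv 3x3 + ReLU) in sequence -- the standard U-Net block
dconv_fwd <- function(x, p) {
  c1 <- conv_fwd(x, p$c1)
  h1 <- pmax(c1$y, 0)
  c2 <- conv_fwd(h1, p$c2)
  y <- pmax(c2$y, 0)
  list(y = y, cache = list(x = c1$x, a1 = c1$y, h1 = h1, a2 = c2$y))
}

dconv_bwd <- function(cache, p, g) {
  g2 <- g * (cache$a2 > 0)
  b2 <- conv_bwd(list(x = cache$h1), p$c2, g2)
  g1 <- b2$gx * (cache$a1 > 0)
  b1 <- conv_bwd(list(x = cache$x), p$c1, g1)
  list(gx = b1$gx, gp = list(c1 = b1$gp, c2 = b2$gp))
}

bind3 <- function(a, b) {
  a <- as_cube(a); b <- as_cube(b)
  array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
}

# zero-pad at the bottom/right to a target spatial size (odd-size decoders)
pad_to <- function(x, tgt) {
  x <- as_cube(x)
  d <- dim(x)
  if (d[1] == tgt[1] && d[2] == tgt[2])
    return(list(y = x, pad = c(0L, 0L)))
  y <- array(0, dim = c(tgt[1], tgt[2], d[3]))
  y[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(y = y, pad = c(tgt[1] - d[1], tgt[2] - d[2]))
}

unpad <- function(g, pad) {
  if (all(pad == 0)) return(g)
  d <- dim(g)
  g[seq_len(d[1] - pad[1]), seq_len(d[2] - pad[2]), , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# channel squeeze-excitation: global average pool -> bottleneck MLP ->
# per-channel sigmoid gate
se_fwd <- function(x, p) {
  d <- dim(x)
  z <- apply(x, 3, mean)
  u1 <- as.numeric(p$fc1$W %*% z + p$fc1$b)
  r <- pmax(u1, 0)
  u2 <- as.numeric(p$fc2$W %*% r + p$fc2$b)
  s <- sigmoid(u2)
  y <- sweep(x, 3, s, "*")
  list(y = y, cache = list(x = x, z = z, u1 = u1, r = r, s = s))
}

se_bwd <- function(cache, p, g) {
  d <- dim(cache$x)
  gx <- sweep(g, 3, cache$s, "*")
  gs <- vapply(seq_len(d[3]),
               function(c) sum(g[, , c] * cache$x[, , c]), numeric(1))
  gu2 <- gs * cache$s * (1 - cache$s)
  gW2 <- gu2 %o% cache$r
  gr <- as.numeric(t(p$fc2$W) %*% gu2)
  gu1 <- gr * (cache$u1 > 0)
  gW1 <- gu1 %o% cache$z
  gz <- as.numeric(t(p$fc1$W) %*% gu1)
  gx <- gx + sweep(array(0, d), 3, gz / (d[1] * d[2]), "+")
  list(gx = gx,
       gp = list(fc1 = list(W = gW1, b = gu1), fc2 = list(W = gW2, b = gu2)))
}

se_param <- function(ch) {
  hidden <- max(1L, ch %/% 2L)
  list(fc1 = dense_param(ch, hidden), fc2 = dense_param(hidden, ch))
}

# Walks `a`, pairing with `b` by name (falling back to position); leaves of
# `a` with no counterpart in `b` (e.g. the conv kernel-size field) pass
# through unchanged.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      bv <- tryCatch(b[[key]], error = function(e) NULL)
      if (is.null(a[[i]]) || is.null(bv)) next
      out[[i]] <- tree_map2(f, a[[i]], bv)
    }
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- tree_map(f, a[[nm]])
    }
    out
  } else if (is.function(a) || is.null(a)) {
    a
  } else {
    f(a)
  }
}

# numeric leaves only (drops kernel-size integers stored alongside weights)
param_leaves <- function(p, path = "") {
  if (is.list(p)) {
    out <- list()
    nms <- names(p)
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, param_leaves(p[[i]], paste0(path, "/", nm)))
    }
    out
  } else if (is.numeric(p) && path != "" &&
             grepl("/(W|b)$", path)) {
    stats::setNames(list(p), path)
  } else {
    list()
  }
}

count_params <- function(params) sum(lengths(param_leaves(params)))
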