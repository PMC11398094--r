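# Coordinate-convolution U-Net variant ("SkeletonNet" regression): the input
# is concatenated with i/j coordinate channels scaled to [-1, 1]; encoder and
# decoder use residual squeezed blocks (two 3x3 convs + channel squeeze-
# excitation, added to a projected shortcut); each decoder stage passes
# through a channel-squeeze/spatial-excitation (csSE) block and emits a
# 1x1-conv side output; the side outputs are upsampled to input resolution
# and fused by a 1x1 convolution into the single-channel prediction.

rsb_param <- function(cin, cout) {
  list(c1 = conv_param(cin, cout, 3),
       c2 = conv_param(cout, cout, 3),
       se = se_param(cout),
       proj = if (cin != cout) conv_param(cin, cout, 1) else NULL)
}

rsb_fwd <- function(x, p) {
  x <- as_cube(x)
  c1 <- conv_fwd(x, p$c1)
  h1 <- pmax(c1$y, 0)
  c2 <- conv_fwd(h1, p$c2)
  se <- se_fwd(c2$y, p$se)
  if (is.null(p$proj)) {
    sk <- x
    pj <- NULL
  } else {
    pj <- conv_fwd(x, p$proj)
    sk <- pj$y
  }
  pre <- se$y + sk
  list(y = pmax(pre, 0),
       cache = list(x = x, a1 = c1$y, h1 = h1, se = se$cache, pre = pre,
                    pj = pj))
}

rsb_bwd <- function(cache, p, g) {
  gpre <- g * (cache$pre > 0)
  if (is.null(p$proj)) {
    gx_sk <- gpre
    gproj <- NULL
  } else {
    pb <- conv_bwd(cache$pj, p$proj, gpre)
    gx_sk <- pb$gx
    gproj <- pb$gp
  }
  seb <- se_bwd(cache$se, p$se, gpre)
  b2 <- conv_bwd(list(x = cache$h1), p$c2, seb$gx)
  g1 <- b2$gx * (cache$a1 > 0)
  b1 <- conv_bwd(list(x = cache$x), p$c1, g1)
  gp <- list(c1 = b1$gp, c2 = b2$gp, se = seb$gp)
  if (!is.null(gproj)) gp$proj <- gproj
  list(gx = b1$gx + gx_sk, gp = gp)
}

csse_param <- function(ch) {
  list(se = se_param(ch), sconv = conv_param(ch, 1, 1))
}

# elementwise max of the channel-excitation and spatial-excitation branches
csse_fwd <- function(x, p) {
  x <- as_cube(x)
  cse <- se_fwd(x, p$se)
  sc <- conv_fwd(x, p$sconv)
  m <- sigmoid(sc$y[, , 1])
  xs <- sweep(x, c(1, 2), m, "*")
  sel <- cse$y >= xs
  list(y = pmax(cse$y, xs),
       cache = list(x = x, cse = cse$cache, sc = sc, m = m, sel = sel))
}

csse_bwd <- function(cache, p, g) {
  gc <- g * cache$sel
  gs <- g * (1 - cache$sel)
  cb <- se_bwd(cache$cse, p$se, gc)
  gx <- cb$gx + sweep(gs, c(1, 2), cache$m, "*")
  gm <- apply(gs * cache$x, c(1, 2), sum)
  gpre <- gm * cache$m * (1 - cache$m)
  sb <- conv_bwd(cache$sc, p$sconv, gpre)
  list(gx = gx + sb$gx, gp = list(se = cb$gp, sconv = sb$gp))
}

coord_channels <- function(H, W) {
  ii <- if (H > 1) seq(-1, 1, length.out = H) else 0
  jj <- if (W > 1) seq(-1, 1, length.out = W) else 0
  array(c(matrix(ii, H, W), matrix(jj, H, W, byrow = TRUE)),
        dim = c(H, W, 2))
}

sknet_init <- function(in_channels = 3, base_channels = 64, depth = 4) {
  stopifnot(base_channels >= 4, depth >= 2)
  ch <- base_channels * 2^(seq_len(depth) - 1)
  enc <- vector("list", depth)
  cin <- in_channels + 2              # + coordinate channels
  for (i in seq_len(depth)) {
    enc[[i]] <- rsb_param(cin, ch[i])
    cin <- ch[i]
  }
  bott <- rsb_param(ch[depth], 2 * ch[depth])
  dec <- vector("list", depth)
  for (i in seq_len(depth)) {
    above <- if (i == depth) 2 * ch[depth] else ch[i + 1]
    dec[[i]] <- list(up = upconv_param(above, ch[i]),
                     rsb = rsb_param(2 * ch[i], ch[i]),
                     csse = csse_param(ch[i]),
                     side = conv_param(ch[i], 1, 1))
  }
  list(enc = enc, bott = bott, dec = dec,
       fuse = conv_param(depth, 1, 1))
}

sknet_forward <- function(params, x, with_tape = TRUE,
                          return_sides = FALSE) {
  depth <- length(params$enc)
  x <- as_cube(x)
  d <- dim(x)
  x5 <- bind3(x, coord_channels(d[1], d[2]))
  skips <- vector("list", depth)
  enc_c <- vector("list", depth)
  pool_c <- vector("list", depth)
  h <- x5
  for (i in seq_len(depth)) {
    rb <- rsb_fwd(h, params$enc[[i]])
    skips[[i]] <- rb$y
    enc_c[[i]] <- rb$cache
    pl <- maxpool2_fwd_cpp(rb$y)
    pool_c[[i]] <- list(idx = pl$idx, H = dim(rb$y)[1], W = dim(rb$y)[2])
    h <- pl$y
  }
  bt <- rsb_fwd(h, params$bott)
  h <- bt$y
  dec_c <- vector("list", depth)
  sides <- vector("list", depth)
  side_c <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    up <- upconv2_fwd_cpp(h, params$dec[[i]]$up$W, params$dec[[i]]$up$b)
    pc <- pad_to(up, dim(skips[[i]])[1:2])
    cat_in <- bind3(skips[[i]], pc$y)
    rb <- rsb_fwd(cat_in, params$dec[[i]]$rsb)
    cs <- csse_fwd(rb$y, params$dec[[i]]$csse)
    sd <- conv_fwd(cs$y, params$dec[[i]]$side)
    f <- 2^(i - 1)
    sup <- if (f > 1) upsample_nn_cpp(sd$y, f) else sd$y
    sp <- pad_to(sup, d[1:2])
    sides[[i]] <- sp$y
    side_c[[i]] <- list(sd = sd, f = f, H = dim(sd$y)[1], W = dim(sd$y)[2],
                        pad = sp$pad)
    dec_c[[i]] <- list(x_in = h, pad = pc$pad, rsb = rb$cache,
                       csse = cs$cache, skip_ch = dim(skips[[i]])[3])
    h <- cs$y
  }
  side_cat <- Reduce(bind3, sides)
  fu <- conv_fwd(side_cat, params$fuse)
  y <- fu$y[, , 1]
  out <- list(y = y)
  if (return_sides) out$sides <- lapply(sides, function(s) s[, , 1])
  if (with_tape)
    out$tape <- list(enc = enc_c, pool = pool_c, bott = bt$cache,
                     dec = dec_c, side = side_c, fuse = fu)
  out
}

sknet_backward <- function(params, tape, gy) {
  depth <- length(params$enc)
  grads <- list(enc = vector("list", depth), bott = NULL,
                dec = vector("list", depth), fuse = NULL)
  fb <- conv_bwd(tape$fuse, params$fuse, as_cube(gy))
  grads$fuse <- fb$gp
  gsides <- fb$gx                      # H x W x depth
  gskips <- vector("list", depth)
  carry <- NULL                        # gradient w.r.t. h_(i+1)
  for (i in seq_len(depth)) {
    sc <- tape$side[[i]]
    gside <- unpad(gsides[, , i, drop = FALSE], sc$pad)
    if (sc$f > 1) gside <- upsample_nn_bwd_cpp(gside, sc$f, sc$H, sc$W)
    sb <- conv_bwd(sc$sd, params$dec[[i]]$side, gside)
    g <- sb$gx
    if (!is.null(carry)) g <- g + carry
    cb <- csse_bwd(tape$dec[[i]]$csse, params$dec[[i]]$csse, g)
    rb <- rsb_bwd(tape$dec[[i]]$rsb, params$dec[[i]]$rsb, cb$gx)
    nsk <- tape$dec[[i]]$skip_ch
    gcat <- rb$gx
    gskips[[i]] <- gcat[, , seq_len(nsk), drop = FALSE]
    gup <- unpad(gcat[, , -seq_len(nsk), drop = FALSE], tape$dec[[i]]$pad)
    ub <- upconv2_bwd_cpp(tape$dec[[i]]$x_in, params$dec[[i]]$up$W, gup)
    grads$dec[[i]] <- list(up = list(W = ub$gW, b = as.numeric(ub$gb)),
                           rsb = rb$gp, csse = cb$gp, side = sb$gp)
    carry <- ub$gx
  }
  btb <- rsb_bwd(tape$bott, params$bott, carry)
  grads$bott <- btb$gp
  g <- btb$gx
  for (i in rev(seq_len(depth))) {
    gpool <- maxpool2_bwd_cpp(tape$pool[[i]]$idx, g,
                              tape$pool[[i]]$H, tape$pool[[i]]$W)
    g <- gpool + gskips[[i]]
    ecb <- rsb_bwd(tape$enc[[i]], params$enc[[i]], g)
    grads$enc[[i]] <- ecb$gp
    g <- ecb$gx
  }
  grads
}
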