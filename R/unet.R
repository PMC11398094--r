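# U-Net regressor: symmetric encoder-decoder with skip connections and a
# 1x1 regression head. "Same" padding throughout so the output matches the
# input size; odd spatial sizes are floored by pooling and re-matched on the
# way up by asymmetric zero padding after each up-convolution.

unet_init <- function(in_channels = 3, base_channels = 64, depth = 4) {
  stopifnot(base_channels >= 4, depth >= 2)
  ch <- base_channels * 2^(seq_len(depth) - 1)
  enc <- vector("list", depth)
  cin <- in_channels
  for (i in seq_len(depth)) {
    enc[[i]] <- list(c1 = conv_param(cin, ch[i], 3),
                     c2 = conv_param(ch[i], ch[i], 3))
    cin <- ch[i]
  }
  bott <- list(c1 = conv_param(ch[depth], 2 * ch[depth], 3),
               c2 = conv_param(2 * ch[depth], 2 * ch[depth], 3))
  dec <- vector("list", depth)
  for (i in seq_len(depth)) {
    above <- if (i == depth) 2 * ch[depth] else ch[i + 1]
    dec[[i]] <- list(up = upconv_param(above, ch[i]),
                     c1 = conv_param(2 * ch[i], ch[i], 3),
                     c2 = conv_param(ch[i], ch[i], 3))
  }
  list(enc = enc, bott = bott, dec = dec,
       head = conv_param(ch[1], 1, 1))
}

unet_forward <- function(params, x, with_tape = TRUE) {
  depth <- length(params$enc)
  x <- as_cube(x)
  skips <- vector("list", depth)
  enc_c <- vector("list", depth)
  pool_c <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    dc <- dconv_fwd(h, params$enc[[i]])
    skips[[i]] <- dc$y
    enc_c[[i]] <- dc$cache
    pl <- maxpool2_fwd_cpp(dc$y)
    pool_c[[i]] <- list(idx = pl$idx, H = dim(dc$y)[1], W = dim(dc$y)[2])
    h <- pl$y
  }
  bt <- dconv_fwd(h, params$bott)
  h <- bt$y
  dec_c <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    up <- upconv2_fwd_cpp(h, params$dec[[i]]$up$W, params$dec[[i]]$up$b)
    pc <- pad_to(up, dim(skips[[i]])[1:2])
    cat_in <- bind3(skips[[i]], pc$y)
    dc <- dconv_fwd(cat_in, params$dec[[i]])
    dec_c[[i]] <- list(x_in = h, pad = pc$pad, dc = dc$cache,
                       skip_ch = dim(skips[[i]])[3])
    h <- dc$y
  }
  hd <- conv_fwd(h, params$head)
  y <- hd$y[, , 1]
  if (!with_tape) return(list(y = y))
  list(y = y, tape = list(enc = enc_c, pool = pool_c, bott = bt$cache,
                          dec = dec_c, head = hd))
}

unet_backward <- function(params, tape, gy) {
  depth <- length(params$enc)
  grads <- list(enc = vector("list", depth), bott = NULL,
                dec = vector("list", depth), head = NULL)
  hb <- conv_bwd(tape$head, params$head, as_cube(gy))
  grads$head <- hb$gp
  g <- hb$gx
  gskips <- vector("list", depth)
  for (i in seq_len(depth)) {        # reverse of the depth..1 decoder order
    dcb <- dconv_bwd(tape$dec[[i]]$dc, params$dec[[i]], g)
    sc <- tape$dec[[i]]$skip_ch
    gcat <- dcb$gx
    gskips[[i]] <- gcat[, , seq_len(sc), drop = FALSE]
    gup <- unpad(gcat[, , -seq_len(sc), drop = FALSE], tape$dec[[i]]$pad)
    ub <- upconv2_bwd_cpp(tape$dec[[i]]$x_in, params$dec[[i]]$up$W, gup)
    grads$dec[[i]] <- c(dcb$gp,
                        list(up = list(W = ub$gW, b = as.numeric(ub$gb))))
    g <- ub$gx
  }
  btb <- dconv_bwd(tape$bott, params$bott, g)
  grads$bott <- btb$gp
  g <- btb$gx
  for (i in rev(seq_len(depth))) {
    gpool <- maxpool2_bwd_cpp(tape$pool[[i]]$idx, g,
                              tape$pool[[i]]$H, tape$pool[[i]]$W)
    g <- gpool + gskips[[i]]
    ecb <- dconv_bwd(tape$enc[[i]], params$enc[[i]], g)
    grads$enc[[i]] <- ecb$gp
    g <- ecb$gx
  }
  grads
}
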