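# Small CPU-trainable networks for the five pipeline stages, written on top
# of the package's conv/pool/upsample kernels.  Architectures follow the
# stage contracts: softmax classification heads for view and slice
# selection, a shared convolutional frame encoder with a bidirectional
# recurrent layer emitting a phase curve, and encoder-decoder networks with
# skip connections emitting landmark heatmaps or per-pixel class maps.
# Optimization is plain stochastic gradient descent with momentum.

as_cube <- function(x) {
  if (length(dim(x)) == 2) array(x, c(dim(x), 1)) else x
}

he_conv <- function(cin, cout) {
  list(w = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout),
       b = numeric(cout))
}

he_dense <- function(nin, nout) {
  list(w = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# ---- classifier (view / slice selection) -----------------------------------

nn_classifier_init <- function(n_classes, input_px = 128L, cin = 1L) {
  widths <- c(cin, 8L, 16L, 32L, 32L)
  convs <- lapply(seq_len(4), function(i) he_conv(widths[i], widths[i + 1]))
  names(convs) <- paste0("c", seq_len(4))
  flat <- (input_px / 16)^2 * widths[5]
  list(type = "classifier", n_classes = n_classes, input_px = input_px,
       convs = convs, head = he_dense(flat, n_classes))
}

nn_classifier_fw <- function(net, x) {
  x <- as_cube(x)
  cache <- list(x0 = x)
  for (i in seq_along(net$convs)) {
    z <- cpp_conv3_fw(x, net$convs[[i]]$w, net$convs[[i]]$b)
    a <- relu(z)
    p <- cpp_maxpool2_fw(a)
    cache[[paste0("x", i)]] <- x
    cache[[paste0("z", i)]] <- z
    cache[[paste0("idx", i)]] <- p$idx
    cache[[paste0("dim", i)]] <- dim(a)
    x <- p$out
  }
  flat <- as.vector(x)
  logits <- drop(flat %*% net$head$w) + net$head$b
  cache$flat <- flat
  cache$top_dim <- dim(x)
  list(probs = softmax(logits), logits = logits, cache = cache)
}

nn_classifier_bw <- function(net, cache, dlogits) {
  g <- list(convs = stats::setNames(vector("list", 4), paste0("c", 1:4)),
            head = list())
  g$head$w <- outer(cache$flat, dlogits)
  g$head$b <- dlogits
  dx <- array(as.vector(net$head$w %*% dlogits), cache$top_dim)
  for (i in rev(seq_along(net$convs))) {
    d <- cache[[paste0("dim", i)]]
    da <- cpp_maxpool2_bw(cache[[paste0("idx", i)]], dx, d[1], d[2])
    dz <- da * (cache[[paste0("z", i)]] > 0)
    bw <- cpp_conv3_bw(cache[[paste0("x", i)]], net$convs[[i]]$w, dz)
    g$convs[[i]] <- list(w = bw$gw, b = bw$gb)
    dx <- bw$gx
  }
  g
}

# ---- U-net (landmark heatmaps / segmentation) ------------------------------

nn_unet_init <- function(cin, cout, input_px = 128L) {
  # 3-level encoder-decoder with skip connections; receptive field ~60 px
  # at the input resolution
  list(type = "unet", cin = cin, cout = cout, input_px = input_px,
       enc1 = he_conv(cin, 8L), enc2 = he_conv(8L, 16L),
       enc3 = he_conv(16L, 32L), bott = he_conv(32L, 48L),
       dec3 = he_conv(48L + 32L, 24L), dec2 = he_conv(24L + 16L, 16L),
       dec1 = he_conv(16L + 8L, 8L), head = he_conv(8L, cout))
}

cube_cat <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

nn_unet_fw <- function(net, x) {
  x <- as_cube(x)
  c1z <- cpp_conv3_fw(x, net$enc1$w, net$enc1$b); c1 <- relu(c1z)
  p1 <- cpp_maxpool2_fw(c1)
  c2z <- cpp_conv3_fw(p1$out, net$enc2$w, net$enc2$b); c2 <- relu(c2z)
  p2 <- cpp_maxpool2_fw(c2)
  c3z <- cpp_conv3_fw(p2$out, net$enc3$w, net$enc3$b); c3 <- relu(c3z)
  p3 <- cpp_maxpool2_fw(c3)
  bz <- cpp_conv3_fw(p3$out, net$bott$w, net$bott$b); bb <- relu(bz)
  u3 <- cpp_upsample2_fw(bb)
  cat3 <- cube_cat(u3, c3)
  d3z <- cpp_conv3_fw(cat3, net$dec3$w, net$dec3$b); d3 <- relu(d3z)
  u2 <- cpp_upsample2_fw(d3)
  cat2 <- cube_cat(u2, c2)
  d2z <- cpp_conv3_fw(cat2, net$dec2$w, net$dec2$b); d2 <- relu(d2z)
  u1 <- cpp_upsample2_fw(d2)
  cat1 <- cube_cat(u1, c1)
  d1z <- cpp_conv3_fw(cat1, net$dec1$w, net$dec1$b); d1 <- relu(d1z)
  out <- cpp_conv3_fw(d1, net$head$w, net$head$b)
  list(out = out,
       cache = list(x = x, c1z = c1z, c1 = c1, p1 = p1, c2z = c2z, c2 = c2,
                    p2 = p2, c3z = c3z, c3 = c3, p3 = p3, bz = bz,
                    cat3 = cat3, d3z = d3z, cat2 = cat2, d2z = d2z,
                    cat1 = cat1, d1z = d1z, d1 = d1))
}

nn_unet_bw <- function(net, cache, dout) {
  g <- list()
  bwh <- cpp_conv3_bw(cache$d1, net$head$w, dout)
  g$head <- list(w = bwh$gw, b = bwh$gb)
  dd1 <- bwh$gx * (cache$d1z > 0)
  bw1 <- cpp_conv3_bw(cache$cat1, net$dec1$w, dd1)
  g$dec1 <- list(w = bw1$gw, b = bw1$gb)
  du1 <- bw1$gx[, , 1:16, drop = FALSE]           # upsampled dec2 part
  dc1_skip <- bw1$gx[, , 16 + seq_len(dim(cache$c1)[3]), drop = FALSE]
  dd2 <- cpp_upsample2_bw(du1) * (cache$d2z > 0)
  bw2 <- cpp_conv3_bw(cache$cat2, net$dec2$w, dd2)
  g$dec2 <- list(w = bw2$gw, b = bw2$gb)
  du2 <- bw2$gx[, , 1:24, drop = FALSE]           # upsampled dec3 part
  dc2_skip <- bw2$gx[, , 24 + seq_len(dim(cache$c2)[3]), drop = FALSE]
  dd3 <- cpp_upsample2_bw(du2) * (cache$d3z > 0)
  bw3 <- cpp_conv3_bw(cache$cat3, net$dec3$w, dd3)
  g$dec3 <- list(w = bw3$gw, b = bw3$gb)
  du3 <- bw3$gx[, , 1:48, drop = FALSE]           # upsampled bottleneck part
  dc3_skip <- bw3$gx[, , 48 + seq_len(dim(cache$c3)[3]), drop = FALSE]
  db <- cpp_upsample2_bw(du3) * (cache$bz > 0)
  bwb <- cpp_conv3_bw(cache$p3$out, net$bott$w, db)
  g$bott <- list(w = bwb$gw, b = bwb$gb)
  dc3 <- cpp_maxpool2_bw(cache$p3$idx, bwb$gx, dim(cache$c3)[1],
                         dim(cache$c3)[2]) + dc3_skip
  dz3 <- dc3 * (cache$c3z > 0)
  bwe3 <- cpp_conv3_bw(cache$p2$out, net$enc3$w, dz3)
  g$enc3 <- list(w = bwe3$gw, b = bwe3$gb)
  dc2 <- cpp_maxpool2_bw(cache$p2$idx, bwe3$gx, dim(cache$c2)[1],
                         dim(cache$c2)[2]) + dc2_skip
  dz2 <- dc2 * (cache$c2z > 0)
  bwe2 <- cpp_conv3_bw(cache$p1$out, net$enc2$w, dz2)
  g$enc2 <- list(w = bwe2$gw, b = bwe2$gb)
  dc1 <- cpp_maxpool2_bw(cache$p1$idx, bwe2$gx, dim(cache$c1)[1],
                         dim(cache$c1)[2]) + dc1_skip
  dz1 <- dc1 * (cache$c1z > 0)
  bwe1 <- cpp_conv3_bw(cache$x, net$enc1$w, dz1)
  g$enc1 <- list(w = bwe1$gw, b = bwe1$gb)
  g
}

# ---- phase network: shared frame encoder + bidirectional RNN ---------------

nn_phase_init <- function(n_frames = 30L, frame_px = 32L, hidden = 16L) {
  feat <- 16L
  list(type = "phase", n_frames = n_frames, frame_px = frame_px,
       hidden = hidden, feat = feat,
       conv1 = he_conv(1L, 8L), conv2 = he_conv(8L, feat),
       rnn_f = list(wx = matrix(rnorm(feat * hidden, 0, sqrt(1 / feat)), feat, hidden),
                    wh = matrix(rnorm(hidden * hidden, 0, sqrt(1 / hidden)), hidden, hidden),
                    b = numeric(hidden)),
       rnn_b = list(wx = matrix(rnorm(feat * hidden, 0, sqrt(1 / feat)), feat, hidden),
                    wh = matrix(rnorm(hidden * hidden, 0, sqrt(1 / hidden)), hidden, hidden),
                    b = numeric(hidden)),
       # head sees the recurrent states plus the frame features directly (a
       # skip path that eases optimization of the recurrent layers)
       head = he_dense(2L * hidden + feat, 1L))
}

# x: n_frames x px x px array -> per-frame features (n_frames x feat)
nn_phase_encode_fw <- function(net, x) {
  n <- dim(x)[1]
  feats <- matrix(0, n, net$feat)
  caches <- vector("list", n)
  for (t in seq_len(n)) {
    f <- array(x[t, , ], c(dim(x)[2], dim(x)[3], 1))
    z1 <- cpp_conv3_fw(f, net$conv1$w, net$conv1$b); a1 <- relu(z1)
    p1 <- cpp_maxpool2_fw(a1)
    z2 <- cpp_conv3_fw(p1$out, net$conv2$w, net$conv2$b); a2 <- relu(z2)
    p2 <- cpp_maxpool2_fw(a2)
    feats[t, ] <- apply(p2$out, 3, mean)  # global average pooling
    caches[[t]] <- list(f = f, z1 = z1, a1dim = dim(a1), p1 = p1, z2 = z2,
                        a2dim = dim(a2), p2 = p2)
  }
  list(feats = feats, caches = caches)
}

rnn_fw <- function(p, feats) {
  n <- nrow(feats)
  h <- matrix(0, n, ncol(p$wh))
  prev <- numeric(ncol(p$wh))
  for (t in seq_len(n)) {
    h[t, ] <- tanh(drop(feats[t, ] %*% p$wx) + drop(prev %*% p$wh) + p$b)
    prev <- h[t, ]
  }
  h
}

rnn_bw <- function(p, feats, h, dh) {
  n <- nrow(feats)
  g <- list(wx = p$wx * 0, wh = p$wh * 0, b = p$b * 0)
  dfeats <- feats * 0
  carry <- numeric(ncol(p$wh))
  for (t in rev(seq_len(n))) {
    dt <- (dh[t, ] + carry) * (1 - h[t, ]^2)
    g$wx <- g$wx + outer(feats[t, ], dt)
    prev <- if (t > 1) h[t - 1, ] else numeric(ncol(p$wh))
    g$wh <- g$wh + outer(prev, dt)
    g$b <- g$b + dt
    dfeats[t, ] <- drop(p$wx %*% dt)
    carry <- drop(p$wh %*% dt)
  }
  list(g = g, dfeats = dfeats)
}

nn_phase_fw <- function(net, x) {
  enc <- nn_phase_encode_fw(net, x)
  hf <- rnn_fw(net$rnn_f, enc$feats)
  fr <- enc$feats[rev(seq_len(nrow(enc$feats))), , drop = FALSE]
  hb_r <- rnn_fw(net$rnn_b, fr)
  hb <- hb_r[rev(seq_len(nrow(hb_r))), , drop = FALSE]
  H <- cbind(hf, hb, enc$feats)
  logits <- drop(H %*% net$head$w) + net$head$b
  curve <- 1 / (1 + exp(-logits))
  list(curve = curve, cache = list(enc = enc, hf = hf, hb = hb, hb_r = hb_r,
                                   H = H, curve = curve))
}

nn_phase_bw <- function(net, x, cache, dcurve) {
  dlog <- dcurve * cache$curve * (1 - cache$curve)
  g <- list()
  g$head <- list(w = crossprod(cache$H, matrix(dlog)), b = sum(dlog))
  dH <- outer(dlog, drop(net$head$w))
  hid <- net$hidden
  rf <- rnn_bw(net$rnn_f, cache$enc$feats, cache$hf,
               dH[, seq_len(hid), drop = FALSE])
  fr <- cache$enc$feats[rev(seq_len(nrow(cache$enc$feats))), , drop = FALSE]
  dHb <- dH[, hid + seq_len(hid), drop = FALSE]
  rb <- rnn_bw(net$rnn_b, fr, cache$hb_r,
               dHb[rev(seq_len(nrow(dHb))), , drop = FALSE])
  g$rnn_f <- rf$g
  g$rnn_b <- rb$g
  dfeats <- rf$dfeats + rb$dfeats[rev(seq_len(nrow(rb$dfeats))), , drop = FALSE] +
    dH[, 2 * hid + seq_len(net$feat), drop = FALSE]  # skip path
  # back through the shared frame encoder
  g$conv1 <- list(w = net$conv1$w * 0, b = net$conv1$b * 0)
  g$conv2 <- list(w = net$conv2$w * 0, b = net$conv2$b * 0)
  for (t in seq_len(nrow(dfeats))) {
    cc <- cache$enc$caches[[t]]
    pd <- dim(cc$p2$out)
    dgap <- array(rep(dfeats[t, ], each = pd[1] * pd[2]) / (pd[1] * pd[2]), pd)
    da2 <- cpp_maxpool2_bw(cc$p2$idx, dgap, cc$a2dim[1], cc$a2dim[2])
    dz2 <- da2 * (cc$z2 > 0)
    bw2 <- cpp_conv3_bw(cc$p1$out, net$conv2$w, dz2)
    g$conv2$w <- g$conv2$w + bw2$gw
    g$conv2$b <- g$conv2$b + bw2$gb
    da1 <- cpp_maxpool2_bw(cc$p1$idx, bw2$gx, cc$a1dim[1], cc$a1dim[2])
    dz1 <- da1 * (cc$z1 > 0)
    bw1 <- cpp_conv3_bw(cc$f, net$conv1$w, dz1)
    g$conv1$w <- g$conv1$w + bw1$gw
    g$conv1$b <- g$conv1$b + bw1$gb
  }
  g
}

# ---- generic parameter bookkeeping -----------------------------------------

# recursively walk a net/grad structure collecting numeric leaves
nn_leaves <- function(x, path = character()) {
  if (is.numeric(x)) return(stats::setNames(list(x), paste(path, collapse = "$")))
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    out <- list()
    for (k in seq_along(x)) {
      nm <- nms[k]
      if (nm %in% c("type", "n_classes", "input_px", "cin", "cout", "n_frames",
                    "frame_px", "hidden", "feat")) next
      out <- c(out, nn_leaves(x[[k]], c(path, nm)))
    }
    return(out)
  }
  list()
}

nn_update_sgd <- function(net, grads, vel, lr, momentum) {
  gl <- nn_leaves(grads)
  nl <- nn_leaves(net)
  for (key in names(gl)) {
    if (is.null(vel[[key]])) vel[[key]] <- gl[[key]] * 0
    vel[[key]] <- momentum * vel[[key]] - lr * gl[[key]]
    nl[[key]] <- nl[[key]] + vel[[key]]
  }
  # write leaves back
  for (key in names(nl)) {
    parts <- strsplit(key, "$", fixed = TRUE)[[1]]
    net <- nn_assign(net, parts, nl[[key]])
  }
  list(net = net, vel = vel)
}

nn_assign <- function(x, parts, value) {
  if (length(parts) == 1) {
    x[[parts]] <- value
    return(x)
  }
  x[[parts[1]]] <- nn_assign(x[[parts[1]]], parts[-1], value)
  x
}
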