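# Neural-network operations on the tape: convolution, batch/layer norm,
# pooling, upsampling, weight standardization, windowed self-attention.

# Convolutions default to strict double precision. The compiled
# single-precision kernels (options(yologinseng.conv_double = FALSE)) are
# faster but their rounding noise is amplified by near-degenerate batch
# statistics early in training, so they are reserved for inference-style
# workloads.
conv_single <- function() isFALSE(getOption("yologinseng.conv_double", TRUE))

ag_conv <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- vof(x); wv <- vof(w); bv <- if (is.null(b)) NULL else vof(b)
  single <- conv_single()
  fw <- if (single) cpp_conv2d_f else cpp_conv2d
  y <- fw(xv, dim(xv), wv, dim(wv), bv, stride, pad, dil)
  inputs <- list(x, w)
  if (!is.null(b)) inputs <- c(inputs, list(b))
  ag_op(y, inputs, function(g) {
    need_gx <- is_node(x)
    bwf <- if (single) cpp_conv2d_bw_f else cpp_conv2d_bw
    bw <- bwf(xv, dim(xv), wv, dim(wv), g, need_gx, !is.null(b), stride, pad, dil)
    out <- list(if (need_gx) bw$gx else NULL, bw$gw)
    if (!is.null(b)) out <- c(out, list(as.numeric(bw$gb)))
    out
  })
}

# per-channel statistics over (H, W, N)
channel_stats <- function(x) cpp_channel_stats(x, dim(x))

bc_channel <- function(v, d) {
  # broadcast a length-C vector over (H, W, C, N)
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

ag_bn_train <- function(x, gamma, beta, eps = 1e-5) {
  xv <- vof(x); gv <- as.numeric(vof(gamma)); bv <- as.numeric(vof(beta))
  d <- dim(xv); m <- d[1] * d[2] * d[4]
  st <- channel_stats(xv)
  mu <- st$mean; var_b <- pmax(st$m2 - mu * mu, 0)
  s <- sqrt(var_b + eps)
  xhat <- cpp_chan_affine(xv, d, 1 / s, -mu / s)
  y <- cpp_chan_affine(xhat, d, gv, bv)
  node <- ag_op(y, list(x, gamma, beta), function(g) {
    st2 <- cpp_chan_stats2(g, xhat, d)
    dgamma <- st2$mgh * m
    dbeta  <- st2$mg * m
    gx <- cpp_chan_affine(g - cpp_bc_mul(xhat, d, st2$mgh, c(1L, 1L, d[3], 1L)),
                          d, gv / s, -st2$mg * gv / s)
    list(gx, dgamma, dbeta)
  })
  attr_stats <- list(mean = mu, var = var_b * m / max(m - 1, 1))  # unbiased for running
  list(out = node, stats = attr_stats)
}

ag_bn_eval <- function(x, gamma, beta, rmean, rvar, eps = 1e-5) {
  xv <- vof(x); gv <- as.numeric(vof(gamma)); bv <- as.numeric(vof(beta))
  d <- dim(xv)
  inv <- 1 / sqrt(rvar + eps)
  a <- gv * inv
  y <- cpp_chan_affine(xv, d, a, bv - rmean * a)
  ag_op(y, list(x, gamma, beta), function(g) {
    xhat <- cpp_chan_affine(xv, d, inv, -rmean * inv)
    st2 <- cpp_chan_stats2(g, xhat, d)
    m <- d[1] * d[2] * d[4]
    list(cpp_chan_affine(g, d, a, numeric(d[3])), st2$mgh * m, st2$mg * m)
  })
}

ag_maxpool <- function(x, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- k %/% 2L
  xv <- vof(x)
  r <- cpp_maxpool(xv, dim(xv), k, stride, pad)
  ag_op(r$y, list(x), function(g) list(cpp_maxpool_bw(g, r$idx, dim(xv))))
}

ag_upsample <- function(x, scale = 2L) {
  xv <- vof(x)
  y <- cpp_upsample_nearest(xv, dim(xv), scale)
  ag_op(y, list(x), function(g) list(cpp_upsample_nearest_bw(g, dim(xv), scale)))
}

ag_avgpool_same <- function(x, k = 5L) {
  xv <- vof(x)
  y <- cpp_avgpool_same(xv, dim(xv), k)
  ag_op(y, list(x), function(g) list(cpp_avgpool_same_bw(g, dim(xv), k)))
}

# mean over width -> (H, 1, C, N); mean over height -> (1, W, C, N)
ag_pool_w <- function(x) {
  xv <- vof(x); d <- dim(xv)
  y <- dim_sum(xv, 2L) / d[2]
  ag_op(y, list(x), function(g) list(bc_expand(g, d) / d[2]))
}

ag_pool_h <- function(x) {
  xv <- vof(x); d <- dim(xv)
  y <- dim_sum(xv, 1L) / d[1]
  ag_op(y, list(x), function(g) list(bc_expand(g, d) / d[1]))
}

# LayerNorm over the channel dimension of an (H, W, C, N) map
ag_layernorm_c <- function(x, gamma, beta, eps = 1e-5) {
  xv <- vof(x); gv <- as.numeric(vof(gamma)); bv <- as.numeric(vof(beta))
  d <- dim(xv); C <- d[3]
  xp <- aperm(xv, c(3L, 1L, 2L, 4L)); dim(xp) <- c(C, prod(d[-3]))
  mu <- colMeans(xp)
  u <- xp - rep(mu, each = C)
  var_b <- colMeans(u * u)
  s <- sqrt(var_b + eps)
  xhat <- u / rep(s, each = C)
  yp <- xhat * gv + bv
  dim(yp) <- c(C, d[1], d[2], d[4])
  y <- aperm(yp, c(2L, 3L, 1L, 4L))
  ag_op(y, list(x, gamma, beta), function(g) {
    gp <- aperm(g, c(3L, 1L, 2L, 4L)); dim(gp) <- c(C, prod(d[-3]))
    gg <- gp * gv
    dgamma <- rowSums(gp * xhat)
    dbeta <- rowSums(gp)
    mg <- colMeans(gg)
    mgx <- colMeans(gg * xhat)
    gx <- (gg - rep(mg, each = C) - xhat * rep(mgx, each = C)) / rep(s, each = C)
    dim(gx) <- c(C, d[1], d[2], d[4])
    list(aperm(gx, c(2L, 3L, 1L, 4L)), dgamma, dbeta)
  })
}

# Adaptive weight standardization (per output channel, unbiased sd + 1e-5)
ag_aws_weight <- function(w, wg, wb) {
  wv <- vof(w); gv <- vof(wg); bv <- vof(wb)
  d <- dim(wv); K <- prod(d[1:3]); Co <- d[4]
  wm <- wv; dim(wm) <- c(K, Co)
  mu <- colMeans(wm)
  u <- wm - rep(mu, each = K)
  sd_raw <- sqrt(colSums(u * u) / max(K - 1, 1))
  s <- sd_raw + 1e-5
  yhat <- u / rep(s, each = K)
  ym <- yhat * rep(gv, each = K) + rep(bv, each = K)
  dim(ym) <- d
  ag_op(ym, list(w, wg, wb), function(g) {
    gm <- g; dim(gm) <- c(K, Co)
    dg <- colSums(gm * yhat)
    db <- colSums(gm)
    gg <- gm * rep(gv, each = K)
    mg <- colMeans(gg)
    su <- colSums(gg * u)
    denom <- pmax((K - 1) * sd_raw * s * s, 1e-12)
    gw <- (gg - rep(mg, each = K)) / rep(s, each = K) -
      u * rep(su / denom, each = K)
    dim(gw) <- d
    list(gw, dg, db)
  })
}

ag_bce_logits <- function(z, target) {
  zv <- vof(z); tv <- vof(target)
  val <- pmax(zv, 0) - zv * tv + log1p(exp(-abs(zv)))
  ag_op(val, list(z), function(g) {
    list(g * (1 / (1 + exp(-zv)) - tv))
  })
}

# ---- windowed multi-head self-attention -----------------------------------

# relative-position index table (ws^2 x ws^2 of 1-based indices into the
# (2 ws - 1)^2 bias vector), following the Swin convention
rel_pos_index <- function(ws) {
  coords <- expand.grid(h = seq_len(ws) - 1L, w = seq_len(ws) - 1L)
  # token order must match our window flattening: h fastest within a window
  dh <- outer(coords$h, coords$h, `-`) + ws - 1L
  dw <- outer(coords$w, coords$w, `-`) + ws - 1L
  dh * (2L * ws - 1L) + dw + 1L
}

# attention mask (list of nwin matrices ws^2 x ws^2, 0 or -100) for shifted
# windows on an Hp x Wp padded map
shift_attn_mask <- function(Hp, Wp, ws, shift) {
  seg <- function(n) {
    id <- integer(n)
    id[seq_len(n - ws)] <- 0L
    if (ws - shift > 0) id[(n - ws + 1L):(n - shift)] <- 1L
    id[(n - shift + 1L):n] <- 2L
    id
  }
  hid <- seg(Hp); wid <- seg(Wp)
  img <- outer(hid, wid, function(a, b) a * 3L + b)
  nh <- Hp %/% ws; nw <- Wp %/% ws
  masks <- vector("list", nh * nw)
  k <- 1L
  for (j in seq_len(nw)) for (i in seq_len(nh)) {
    blk <- img[((i - 1L) * ws + 1L):(i * ws), ((j - 1L) * ws + 1L):(j * ws)]
    v <- as.integer(blk)  # h fastest
    m <- outer(v, v, function(a, b) ifelse(a == b, 0, -100))
    masks[[k]] <- m
    k <- k + 1L
  }
  masks
}

# x: (H, W, 3*dim, N) packed q|k|v along channels. rbias: (heads, (2ws-1)^2).
# Cyclic shift, window partition, per-window multi-head attention, reverse.
ag_window_attention <- function(x, rbias, dim_, heads, ws, shift = 0L) {
  xv <- vof(x); rv <- vof(rbias)
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[4]
  dh <- dim_ %/% heads
  scale <- 1 / sqrt(dh)
  Hp <- ceiling(H / ws) * ws; Wp <- ceiling(W / ws) * ws
  padded <- Hp > H || Wp > W
  xp <- if (padded) {
    tmp <- array(0, dim = c(Hp, Wp, 3L * dim_, N))
    tmp[1:H, 1:W, , ] <- xv
    tmp
  } else xv
  if (shift > 0L) {
    hidx <- c((shift + 1L):Hp, 1:shift); widx <- c((shift + 1L):Wp, 1:shift)
    xp <- xp[hidx, widx, , , drop = FALSE]
  }
  nh <- Hp %/% ws; nw <- Wp %/% ws; nwin <- nh * nw
  # to windows: (ws^2, 3dim, nwin, N)
  dim(xp) <- c(ws, nh, ws, nw, 3L * dim_, N)
  xw <- aperm(xp, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(xw) <- c(ws * ws, 3L * dim_, nwin, N)
  ridx <- rel_pos_index(ws)
  masks <- if (shift > 0L) shift_attn_mask(Hp, Wp, ws, shift) else NULL
  T_ <- ws * ws
  out <- array(0, dim = c(T_, dim_, nwin, N))
  cache <- vector("list", nwin * N)
  ci <- 0L
  for (n in seq_len(N)) for (wi in seq_len(nwin)) {
    ci <- ci + 1L
    blk <- matrix(xw[, , wi, n], T_, 3L * dim_)
    heads_cache <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      q <- blk[, cols, drop = FALSE]
      k <- blk[, dim_ + cols, drop = FALSE]
      v <- blk[, 2L * dim_ + cols, drop = FALSE]
      logits <- tcrossprod(q, k) * scale
      B <- matrix(rv[h, ridx], T_, T_)
      logits <- logits + B
      if (!is.null(masks)) logits <- logits + masks[[wi]]
      logits <- logits - apply(logits, 1L, max)
      e <- exp(logits)
      attn <- e / rowSums(e)
      out[, cols, wi, n] <- attn %*% v
      heads_cache[[h]] <- list(q = q, k = k, v = v, attn = attn)
    }
    cache[[ci]] <- heads_cache
  }
  # windows back to map
  dim(out) <- c(ws, ws, dim_, nh, nw, N)
  om <- aperm(out, c(1L, 4L, 2L, 5L, 3L, 6L))
  dim(om) <- c(Hp, Wp, dim_, N)
  if (shift > 0L) {
    hidx2 <- c((Hp - shift + 1L):Hp, 1:(Hp - shift))
    widx2 <- c((Wp - shift + 1L):Wp, 1:(Wp - shift))
    om <- om[hidx2, widx2, , , drop = FALSE]
  }
  y <- om[1:H, 1:W, , , drop = FALSE]

  ag_op(y, list(x, rbias), function(g) {
    gp <- if (padded) {
      tmp <- array(0, dim = c(Hp, Wp, dim_, N)); tmp[1:H, 1:W, , ] <- g; tmp
    } else g
    if (shift > 0L) {
      hidx <- c((shift + 1L):Hp, 1:shift); widx <- c((shift + 1L):Wp, 1:shift)
      gp <- gp[hidx, widx, , , drop = FALSE]
    }
    dim(gp) <- c(ws, nh, ws, nw, dim_, N)
    gw <- aperm(gp, c(1L, 3L, 5L, 2L, 4L, 6L))
    dim(gw) <- c(T_, dim_, nwin, N)
    gxw <- array(0, dim = c(T_, 3L * dim_, nwin, N))
    grb <- array(0, dim = dim(rv))
    ci <- 0L
    for (n in seq_len(N)) for (wi in seq_len(nwin)) {
      ci <- ci + 1L
      hc <- cache[[ci]]
      for (h in seq_len(heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        go <- matrix(gw[, cols, wi, n], T_, dh)
        a <- hc[[h]]$attn
        gv_ <- crossprod(a, go)                       # T x dh
        gattn <- tcrossprod(go, hc[[h]]$v)            # T x T
        gl <- a * (gattn - rowSums(gattn * a))        # softmax backward
        acc <- rowsum(as.numeric(gl), group = as.integer(ridx))
        grb[h, as.integer(rownames(acc))] <- grb[h, as.integer(rownames(acc))] + acc[, 1]
        gq <- (gl %*% hc[[h]]$k) * scale
        gk <- crossprod(gl, hc[[h]]$q) * scale
        gxw[, cols, wi, n] <- gxw[, cols, wi, n] + gq
        gxw[, dim_ + cols, wi, n] <- gxw[, dim_ + cols, wi, n] + gk
        gxw[, 2L * dim_ + cols, wi, n] <- gxw[, 2L * dim_ + cols, wi, n] + gv_
      }
    }
    dim(gxw) <- c(ws, ws, 3L * dim_, nh, nw, N)
    gm <- aperm(gxw, c(1L, 4L, 2L, 5L, 3L, 6L))
    dim(gm) <- c(Hp, Wp, 3L * dim_, N)
    if (shift > 0L) {
      hidx2 <- c((Hp - shift + 1L):Hp, 1:(Hp - shift))
      widx2 <- c((Wp - shift + 1L):Wp, 1:(Wp - shift))
      gm <- gm[hidx2, widx2, , , drop = FALSE]
    }
    list(gm[1:H, 1:W, , , drop = FALSE], grb)
  })
}
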