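# The reusable attention/convolution operators composed by C3f-RN:
# SimAM, Coordinate Attention, Switchable Atrous Convolution, Swin stage.

#' Batch-normalisation forward transform.
#'
#' Applies `y = gamma * (x - mu) / sqrt(sigma^2 + eps) + beta` per channel.
#' The per-channel scale `gamma` is the channel-importance signal the
#' slimming pipeline sparsifies and thresholds.
#'
#' @param x feature map, array with dim `c(H, W, C, N)`
#' @param state list with per-channel numeric vectors `gamma`, `beta`, `mean`,
#'   `sd` and scalar `eps > 0`
#' @return array of the same shape as `x`
#' @examples
#' x <- array(3, c(1, 1, 1, 1))
#' st <- list(gamma = 2, beta = 0.5, mean = 1, sd = sqrt(3.99), eps = 0.01)
#' bn_forward(x, st)  # 2.5
#' @export
bn_forward <- function(x, state) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[3]
  if (length(state$gamma) != C || length(state$beta) != C ||
      length(state$mean) != C || length(state$sd) != C)
    stop("bn_forward: channel count of x and state disagree")
  if (!is.numeric(state$eps) || state$eps <= 0)
    stop("bn_forward: eps must be a positive number")
  if (any(state$sd < 0)) stop("bn_forward: sd must be non-negative")
  d <- dim(x)
  a <- state$gamma / sqrt(state$sd^2 + state$eps)
  b <- state$beta - state$mean * a
  x * bc_channel(a, d) + bc_channel(b, d)
}

#' SimAM parameter-free attention.
#'
#' Weights every activation by a sigmoid-gated energy score derived from its
#' squared deviation from the channel mean; adds zero learnable parameters.
#' Spatially constant channels receive a uniform gate.
#'
#' @param x feature map `c(H, W, C, N)` (array or tape node)
#' @param lambda stability constant of the energy denominator
#' @return gated feature map of the same shape
#' @export
simam <- function(x, lambda = 1e-4) {
  xv <- vof(x)
  d <- dim(xv)
  if (d[1] * d[2] < 2L) stop("simam: needs at least 2 spatial positions per channel")
  HW <- d[1] * d[2]; n1 <- HW - 1L
  xm <- xv; dim(xm) <- c(HW, d[3] * d[4])
  mu <- colMeans(xm)
  u <- xm - rep(mu, each = HW)
  dsq <- u * u
  v <- colSums(dsq) / n1
  denom <- 4 * (v + lambda)
  gate <- dsq / rep(denom, each = HW) + 0.5
  S <- 1 / (1 + exp(-gate))
  ym <- xm * S
  y <- ym; dim(y) <- d
  ag_op(y, list(x), function(g) {
    gm <- g; dim(gm) <- c(HW, d[3] * d[4])
    q <- gm * xm * S * (1 - S)
    A <- 1 / (2 * (v + lambda))
    squ <- colSums(q * u)
    sqd <- colSums(q * dsq)
    coef2 <- sqd / (2 * n1 * (v + lambda)^2)
    gx <- gm * S + u * q * rep(A, each = HW) -
      rep(A * squ / HW, each = HW) - u * rep(coef2, each = HW)
    dim(gx) <- d
    list(gx)
  })
}

# ---- coordinate attention -------------------------------------------------

mk_ca <- function(env, id, c, reduction = 32L) {
  mip <- max(8L, c %/% reduction)
  if (mip < 1L) stop("coordinate attention: reduction leaves no channels")
  list(kind = "ca", id = id, c = c, mip = mip,
       conv1 = mk_conv_bias(env, paste0(id, ".cv1"), c, mip, 1L),
       g  = reg_param(env, paste0(id, ".cv1.bn_g"), mip, "ones"),
       b  = reg_param(env, paste0(id, ".cv1.bn_b"), mip, "zeros"),
       convh = mk_conv_bias(env, paste0(id, ".cvh"), mip, c, 1L),
       convw = mk_conv_bias(env, paste0(id, ".cvw"), mip, c, 1L))
}

fw_ca <- function(m, x, ctx) {
  d <- dim(vof(x)); H <- d[1]; W <- d[2]
  ph <- ag_pool_w(x)                       # (H, 1, C, N)
  pw <- ag_aperm(ag_pool_h(x), c(2L, 1L, 3L, 4L))  # (W, 1, C, N)
  strip <- ag_concat(list(ph, pw), 1L)     # (H + W, 1, C, N)
  z <- fw_conv_bias(m$conv1, strip, ctx)
  z <- fw_bn(m, z, ctx)
  z <- ag_hswish(z)
  zh <- ag_slice(z, 1L, 1:H)
  zw <- ag_aperm(ag_slice(z, 1L, (H + 1L):(H + W)), c(2L, 1L, 3L, 4L))
  ah <- ag_sigmoid(fw_conv_bias(m$convh, zh, ctx))  # (H, 1, C, N)
  aw <- ag_sigmoid(fw_conv_bias(m$convw, zw, ctx))  # (1, W, C, N)
  ag_mul_bc(ag_mul_bc(x, ah), aw)
}

#' Coordinate attention on a feature map.
#'
#' Factorises channel attention into height-wise and width-wise pooled
#' encodings, reduces them through a shared 1x1 bottleneck (clamped to at
#' least 8 channels), and gates the input with the two directional sigmoid
#' maps. Operates with freshly initialised weights unless a prebuilt layer
#' is supplied, so it is primarily a building block and a demonstration
#' surface.
#'
#' @param x feature map `c(H, W, C, N)`
#' @param reduction channel reduction ratio of the bottleneck
#' @param layer optional prebuilt layer state from a model
#' @param seed seed for the throwaway weights when no layer is given
#' @return gated feature map, same shape as `x`
#' @export
coordinate_attention <- function(x, reduction = 32L, layer = NULL, seed = 0L) {
  d <- dim(x)
  if (is.null(layer))
    layer <- standalone_module(function(env) mk_ca(env, "ca", d[3], reduction), seed)
  vof(fw_ca(layer$m, x, layer$ctx))
}

# helper: wrap a single layer into a model env for standalone functional use
standalone_module <- function(builder, seed = 0L) {
  env <- new_model_env()
  m <- builder(env)
  model <- list(env = env)
  init_parameters(model, seed = seed)
  list(m = m, ctx = list(env = env, train = FALSE), model = model)
}

# ---- switchable atrous convolution ----------------------------------------

mk_sac <- function(env, id, c1, c2, rates = c(1L, 3L)) {
  if (any(rates < 1L)) stop("sac: dilation rates must be >= 1")
  if (rates[1] == rates[2])
    warning("sac: equal dilation rates degenerate to a plain convolution")
  list(kind = "sac", id = id, c1 = c1, c2 = c2, k = 3L, rates = as.integer(rates),
       w  = reg_param(env, paste0(id, ".w"), c(3L, 3L, c1, c2), "weight"),
       wg = reg_param(env, paste0(id, ".aws_g"), c2, "ones"),
       wb = reg_param(env, paste0(id, ".aws_b"), c2, "zeros"),
       b  = reg_param(env, paste0(id, ".b"), c2, "zeros"),
       dw = reg_param(env, paste0(id, ".wdiff"), c(3L, 3L, c1, c2), "zeros"),
       sw = reg_param(env, paste0(id, ".switch.w"), c(1L, 1L, c1, 1L), "zeros"),
       sb = reg_param(env, paste0(id, ".switch.b"), 1L, "switch_bias"))
}

fw_sac <- function(m, x, ctx) {
  w_std <- ag_aws_weight(pget(ctx, m$w), pget(ctx, m$wg), pget(ctx, m$wb))
  bias <- pget(ctx, m$b)
  s <- ag_sigmoid(ag_conv(ag_avgpool_same(x, 5L), pget(ctx, m$sw), pget(ctx, m$sb)))
  r1 <- m$rates[1]; r2 <- m$rates[2]
  y1 <- ag_conv(x, w_std, bias, stride = 1L, pad = r1, dil = r1)
  w2 <- ag_add(w_std, pget(ctx, m$dw))
  y2 <- ag_conv(x, w2, bias, stride = 1L, pad = r2, dil = r2)
  ag_add(ag_mul_bc(y1, s), ag_mul_bc(y2, ag_sub(1, s) ))
}

#' Switchable atrous convolution.
#'
#' Runs a weight-standardised 3x3 kernel at two dilation rates (the second
#' branch adds a trainable kernel offset) and blends the two responses per
#' position with a learned switch computed by a 5x5 average pool and a 1x1
#' convolution. The switch initialises to 1, so a fresh layer reproduces the
#' rate-1 branch alone.
#'
#' @param x feature map `c(H, W, C, N)`
#' @param rates length-2 integer dilation rates
#' @param layer optional prebuilt layer state
#' @param seed seed for throwaway weights when no layer is given
#' @return feature map with the same spatial extent as `x`
#' @export
switchable_atrous_conv <- function(x, rates = c(1L, 3L), layer = NULL, seed = 0L) {
  d <- dim(x)
  if (is.null(layer))
    layer <- standalone_module(function(env) mk_sac(env, "sac", d[3], d[3], rates), seed)
  vof(fw_sac(layer$m, x, layer$ctx))
}

# ---- window partition / reverse -------------------------------------------

#' Partition a feature map into non-overlapping square windows.
#'
#' Pads the bottom/right with zeros to a multiple of `win_size`; the inverse
#' ([window_reverse()]) crops back so that partition-then-reverse is the
#' identity on the unpadded region.
#'
#' @param x feature map `c(H, W, C, N)`
#' @param win_size window side length (positive integer)
#' @return array with dim `c(win_size^2, C, n_windows, N)` plus attributes
#'   recording the original and padded extents
#' @export
window_partition <- function(x, win_size) {
  if (win_size <= 0L) stop("win_size must be positive")
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Hp <- ceiling(H / win_size) * win_size
  Wp <- ceiling(W / win_size) * win_size
  if (Hp > H || Wp > W) {
    xp <- array(0, dim = c(Hp, Wp, C, N)); xp[1:H, 1:W, , ] <- x; x <- xp
  }
  nh <- Hp %/% win_size; nw <- Wp %/% win_size
  dim(x) <- c(win_size, nh, win_size, nw, C, N)
  xw <- aperm(x, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(xw) <- c(win_size * win_size, C, nh * nw, N)
  attr(xw, "orig") <- c(H, W); attr(xw, "padded") <- c(Hp, Wp)
  attr(xw, "win_size") <- win_size
  xw
}

#' Reverse a window partition.
#' @param xw output of [window_partition()]
#' @return the original feature map (padding removed)
#' @export
window_reverse <- function(xw) {
  hw <- attr(xw, "orig"); pd <- attr(xw, "padded"); ws <- attr(xw, "win_size")
  d <- dim(xw); C <- d[2]; N <- d[4]
  nh <- pd[1] %/% ws; nw <- pd[2] %/% ws
  dim(xw) <- c(ws, ws, C, nh, nw, N)
  xm <- aperm(xw, c(1L, 4L, 2L, 5L, 3L, 6L))
  dim(xm) <- c(pd[1], pd[2], C, N)
  xm[seq_len(hw[1]), seq_len(hw[2]), , , drop = FALSE]
}

#' Window count of a partition.
#'
#' `num_wins = (H * W) / win_size^2` on the padded map.
#' @param H,W spatial extent
#' @param win_size window side length
#' @export
num_windows <- function(H, W, win_size) {
  (ceiling(H / win_size) * ceiling(W / win_size))
}

# ---- swin stage ------------------------------------------------------------

#' Configuration for a windowed-attention (Swin) stage.
#'
#' @param depth number of attention blocks; must be even so plain and
#'   shifted windows alternate in pairs
#' @param n_heads attention heads; must divide `embed_dim`
#' @param win_size local window side length
#' @param embed_dim channel width inside the stage
#' @param patch_size patch-partition factor (spatial reduction restored by
#'   nearest upsampling at the stage output)
#' @return an object of class `swin_config`
#' @export
swin_config <- function(depth = 2L, n_heads = 8L, win_size = 4L,
                        embed_dim = NULL, patch_size = 4L) {
  if (depth %% 2L != 0L || depth <= 0L)
    stop("swin_config: depth must be a positive even integer")
  if (!is.null(embed_dim) && embed_dim %% n_heads != 0L)
    stop("swin_config: embed_dim must be divisible by n_heads")
  structure(list(depth = as.integer(depth), n_heads = as.integer(n_heads),
                 win_size = as.integer(win_size), embed_dim = embed_dim,
                 patch_size = as.integer(patch_size)),
            class = "swin_config")
}

mk_swin_stage <- function(env, id, c_in, cfg) {
  d <- cfg$embed_dim %||% c_in
  if (d %% cfg$n_heads != 0L) stop("swin stage: embed_dim not divisible by n_heads")
  ps <- cfg$patch_size
  blocks <- lapply(seq_len(cfg$depth), function(i) {
    bid <- paste0(id, ".blk", i)
    list(
      ln1 = mk_layernorm(env, paste0(bid, ".ln1"), d),
      qkv = mk_conv_bias(env, paste0(bid, ".qkv"), d, 3L * d, 1L),
      rb  = reg_param(env, paste0(bid, ".relbias"),
                      c(cfg$n_heads, (2L * cfg$win_size - 1L)^2), "zeros"),
      proj = mk_conv_bias(env, paste0(bid, ".proj"), d, d, 1L),
      ln2 = mk_layernorm(env, paste0(bid, ".ln2"), d),
      fc1 = mk_conv_bias(env, paste0(bid, ".fc1"), d, 4L * d, 1L),
      fc2 = mk_conv_bias(env, paste0(bid, ".fc2"), 4L * d, d, 1L),
      shift = if (i %% 2L == 0L) cfg$win_size %/% 2L else 0L)
  })
  list(kind = "swin_stage", id = id, c1 = c_in, d = d, cfg = cfg, ps = ps,
       embed = reg_param(env, paste0(id, ".embed.w"), c(ps, ps, c_in, d), "weight"),
       blocks = blocks)
}

fw_swin_stage <- function(m, x, ctx) {
  dm <- dim(vof(x)); H <- dm[1]; W <- dm[2]
  ps <- m$ps
  # pad to a multiple of the patch size, then patch-partition via strided conv
  Hp <- ceiling(H / ps) * ps; Wp <- ceiling(W / ps) * ps
  if (Hp > H || Wp > W) {
    xv <- vof(x)
    padfun <- function(v) { t <- array(0, dim = c(Hp, Wp, dim(v)[3], dim(v)[4])); t[1:H, 1:W, , ] <- v; t }
    x <- ag_op(padfun(xv), list(x), function(g) list(g[1:H, 1:W, , , drop = FALSE]))
  }
  z <- ag_conv(x, pget(ctx, m$embed), NULL, stride = ps, pad = 0L)
  cfg <- m$cfg
  for (blk in m$blocks) {
    zi <- z
    z <- ag_layernorm_c(z, pget(ctx, blk$ln1$g), pget(ctx, blk$ln1$b))
    qkv <- fw_conv_bias(blk$qkv, z, ctx)
    att <- ag_window_attention(qkv, pget(ctx, blk$rb), m$d, cfg$n_heads,
                               cfg$win_size, blk$shift)
    att <- fw_conv_bias(blk$proj, att, ctx)
    z <- ag_add(zi, att)
    zi2 <- z
    z <- ag_layernorm_c(z, pget(ctx, blk$ln2$g), pget(ctx, blk$ln2$b))
    z <- fw_conv_bias(blk$fc2, ag_gelu(fw_conv_bias(blk$fc1, z, ctx)), ctx)
    z <- ag_add(zi2, z)
  }
  if (ps > 1L) z <- ag_upsample(z, ps)
  if (Hp > H || Wp > W) z <- ag_slice(ag_slice(z, 1L, 1:H), 2L, 1:W)
  z
}

#' Apply a windowed-attention stage to a feature map.
#'
#' Patch partition (strided embedding convolution), `depth` alternating
#' plain/shifted window attention blocks with per-head relative position
#' biases and 4x MLPs, then nearest upsampling back to the input extent.
#' Output spatial dims always equal the input's.
#'
#' @param x feature map `c(H, W, C, N)`
#' @param cfg a [swin_config()]
#' @param layer optional prebuilt stage from a model
#' @param seed seed for throwaway weights when no layer is given
#' @return feature map `c(H, W, embed_dim, N)`
#' @export
swin_stage <- function(x, cfg = swin_config(), layer = NULL, seed = 0L) {
  d <- dim(x)
  if (is.null(layer))
    layer <- standalone_module(function(env) mk_swin_stage(env, "swin", d[3], cfg), seed)
  vof(fw_swin_stage(layer$m, x, layer$ctx))
}

#' Suggest an attention-head count from the window geometry.
#'
#' Computes `num_wins = H * W / win_size^2` on the padded map and returns
#' `round(sqrt(num_wins))` snapped to the nearest divisor of `embed_dim`
#' (when given). The value is a heuristic starting point; the final head
#' count remains a configuration choice.
#'
#' @param H,W spatial extent of the stage input
#' @param win_size window side length
#' @param embed_dim optional channel width whose divisors constrain the result
#' @return suggested head count (positive integer)
#' @examples
#' heads_from_window(32, 32, 4)  # 64 windows -> 8 heads
#' @export
heads_from_window <- function(H, W, win_size, embed_dim = NULL) {
  stopifnot(H > 0, W > 0, win_size > 0)
  nw <- num_windows(H, W, win_size)
  h <- max(1L, round(sqrt(nw)))
  if (!is.null(embed_dim)) {
    divs <- which(embed_dim %% seq_len(embed_dim) == 0L)
    h <- divs[which.min(abs(divs - h))]
  }
  as.integer(h)
}
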