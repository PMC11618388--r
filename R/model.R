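# Detector assembly: small-width CSP backbone + SPPF + FPN/PAN neck +
# three-scale head, with the four backbone C3 stages optionally replaced by
# C3f-RN modules of matching width.

make_divisible <- function(x, divisor = 8L) as.integer(ceiling(x / divisor) * divisor)

#' Detector model configuration.
#'
#' Width/depth multipliers follow the small ("s") variant convention:
#' `width_mult = 0.50`, `depth_mult = 0.33`. The parameter count of an
#' assembled model is a pure function of this configuration.
#'
#' @param nc number of object classes (>= 1)
#' @param width_mult channel-width multiplier
#' @param depth_mult repeat-count multiplier
#' @param img_size training/inference resolution (multiple of 32)
#' @param c3f_rn `NULL` for the plain baseline, or a list/`swin_config`-like
#'   spec with `depth`, `n_heads`, `win_size` to install C3f-RN in the four
#'   backbone stages
#' @param anchors 3x2 anchor matrix per scale (list of 3), pixel units
#' @return object of class `model_config`
#' @export
model_config <- function(nc = 1L, width_mult = 0.50, depth_mult = 0.33,
                         img_size = 640L, c3f_rn = NULL, anchors = NULL) {
  if (nc < 1L) stop("model_config: nc must be >= 1")
  if (img_size %% 32L != 0L) stop("model_config: img_size must be divisible by 32")
  if (is.null(anchors))
    anchors <- list(matrix(c(10, 13, 16, 30, 33, 23), 3, 2, byrow = TRUE),
                    matrix(c(30, 61, 62, 45, 59, 119), 3, 2, byrow = TRUE),
                    matrix(c(116, 90, 156, 198, 373, 326), 3, 2, byrow = TRUE))
  structure(list(nc = as.integer(nc), width_mult = width_mult,
                 depth_mult = depth_mult, img_size = as.integer(img_size),
                 c3f_rn = c3f_rn, anchors = anchors),
            class = "model_config")
}

mk_c3 <- function(env, id, c1, c2, n, shortcut = TRUE, e = 0.5) {
  c_ <- as.integer(c2 * e)
  list(kind = "c3", id = id, c1 = c1, c2 = c2, c_ = c_, n = n, shortcut = shortcut,
       cv1 = mk_conv_bn(env, paste0(id, ".cv1"), c1, c_, 1L),
       cv2 = mk_conv_bn(env, paste0(id, ".cv2"), c1, c_, 1L),
       cv3 = mk_conv_bn(env, paste0(id, ".cv3"), 2L * c_, c2, 1L),
       m = lapply(seq_len(n), function(i) list(
         cv1 = mk_conv_bn(env, paste0(id, ".m", i, ".cv1"), c_, c_, 1L),
         cv2 = mk_conv_bn(env, paste0(id, ".m", i, ".cv2"), c_, c_, 3L))))
}

fw_c3 <- function(m, x, ctx) {
  a <- fw_conv_bn(m$cv1, x, ctx)
  for (bn in m$m) {
    y <- fw_conv_bn(bn$cv2, fw_conv_bn(bn$cv1, a, ctx), ctx)
    a <- if (m$shortcut) ag_add(a, y) else y
  }
  b <- fw_conv_bn(m$cv2, x, ctx)
  fw_conv_bn(m$cv3, ag_concat(list(a, b), 3L), ctx)
}

mk_sppf <- function(env, id, c1, c2, k = 5L) {
  c_ <- c1 %/% 2L
  list(kind = "sppf", id = id, c1 = c1, c2 = c2, c_ = c_, k = k,
       cv1 = mk_conv_bn(env, paste0(id, ".cv1"), c1, c_, 1L),
       cv2 = mk_conv_bn(env, paste0(id, ".cv2"), 4L * c_, c2, 1L))
}

fw_sppf <- function(m, x, ctx) {
  a <- fw_conv_bn(m$cv1, x, ctx)
  p1 <- ag_maxpool(a, m$k, 1L)
  p2 <- ag_maxpool(p1, m$k, 1L)
  p3 <- ag_maxpool(p2, m$k, 1L)
  fw_conv_bn(m$cv2, ag_concat(list(a, p1, p2, p3), 3L), ctx)
}

mk_detect <- function(env, id, nc, ch, anchors) {
  na <- nrow(anchors[[1]])
  no <- nc + 5L
  list(kind = "detect", id = id, nc = nc, na = na, no = no, ch = ch,
       anchors = anchors,
       convs = lapply(seq_along(ch), function(i)
         mk_conv_bias(env, paste0(id, ".m", i), ch[i], na * no, 1L)))
}

assemble_graph <- function(cfg, use_c3frn) {
  env <- new_model_env()
  gw <- function(c) make_divisible(c * cfg$width_mult, 8L)
  gd <- function(n) max(1L, round(n * cfg$depth_mult))
  backbone_stage <- function(id, c1, c2, n) {
    if (use_c3frn) {
      sw <- cfg$c3f_rn
      swc <- swin_config(depth = sw$depth %||% 2L, n_heads = sw$n_heads %||% 8L,
                         win_size = sw$win_size %||% 4L,
                         patch_size = sw$patch_size %||% 4L)
      mk_c3frn(env, id, c3f_rn_config(c1, c2, n_repeats = n, swin = swc))
    } else mk_c3(env, id, c1, c2, n)
  }
  L <- list()
  add <- function(from, m) L[[length(L) + 1L]] <<- list(from = from, m = m)
  # backbone (indices are 1-based; from = 0 means previous layer)
  add(0, mk_conv_bn(env, "l0", 3L, gw(64), 6L, 2L))
  add(0, mk_conv_bn(env, "l1", gw(64), gw(128), 3L, 2L))
  add(0, backbone_stage("l2", gw(128), gw(128), gd(3)))
  add(0, mk_conv_bn(env, "l3", gw(128), gw(256), 3L, 2L))
  add(0, backbone_stage("l4", gw(256), gw(256), gd(6)))
  add(0, mk_conv_bn(env, "l5", gw(256), gw(512), 3L, 2L))
  add(0, backbone_stage("l6", gw(512), gw(512), gd(9)))
  add(0, mk_conv_bn(env, "l7", gw(512), gw(1024), 3L, 2L))
  add(0, backbone_stage("l8", gw(1024), gw(1024), gd(3)))
  add(0, mk_sppf(env, "l9", gw(1024), gw(1024)))
  # neck
  add(0, mk_conv_bn(env, "l10", gw(1024), gw(512), 1L))
  add(0, list(kind = "upsample"))
  add(c(0, 7), list(kind = "concat"))
  add(0, mk_c3(env, "l13", gw(1024), gw(512), gd(3), shortcut = FALSE))
  add(0, mk_conv_bn(env, "l14", gw(512), gw(256), 1L))
  add(0, list(kind = "upsample"))
  add(c(0, 5), list(kind = "concat"))
  add(0, mk_c3(env, "l17", gw(512), gw(256), gd(3), shortcut = FALSE))
  add(0, mk_conv_bn(env, "l18", gw(256), gw(256), 3L, 2L))
  add(c(0, 15), list(kind = "concat"))
  add(0, mk_c3(env, "l20", gw(512), gw(512), gd(3), shortcut = FALSE))
  add(0, mk_conv_bn(env, "l21", gw(512), gw(512), 3L, 2L))
  add(c(0, 11), list(kind = "concat"))
  add(0, mk_c3(env, "l23", gw(1024), gw(1024), gd(3), shortcut = FALSE))
  add(c(18, 21, 24), mk_detect(env, "l24", cfg$nc,
                               c(gw(256), gw(512), gw(1024)), cfg$anchors))
  list(env = env, layers = L, cfg = cfg,
       strides = c(8L, 16L, 32L), variant = if (use_c3frn) "c3f_rn" else "baseline")
}

#' Assemble the plain small-width baseline detector.
#' @param cfg a [model_config()] with `c3f_rn = NULL`
#' @return a model object (weights not yet materialised; see
#'   [init_parameters()])
#' @export
assemble_baseline <- function(cfg = model_config()) {
  if (!is.null(cfg$c3f_rn))
    stop("assemble_baseline: cfg carries a c3f_rn block; use assemble_yolo_ginseng")
  assemble_graph(cfg, use_c3frn = FALSE)
}

#' Assemble the YOLO-Ginseng detector.
#'
#' The baseline graph with each of the four backbone C3 stages replaced by a
#' C3f-RN module of matching width and repeat count; neck and head untouched.
#' @param cfg a [model_config()] whose `c3f_rn` list supplies `depth`,
#'   `n_heads`, `win_size` (and optionally `patch_size`)
#' @return a model object
#' @export
assemble_yolo_ginseng <- function(cfg = model_config(c3f_rn = list(depth = 2L, n_heads = 8L, win_size = 4L))) {
  if (is.null(cfg$c3f_rn))
    stop("assemble_yolo_ginseng: cfg$c3f_rn must be supplied")
  gw <- function(c) make_divisible(c * cfg$width_mult, 8L)
  heads <- cfg$c3f_rn$n_heads %||% 8L
  for (c in c(128, 256, 512, 1024)) {
    h <- gw(c) %/% 2L
    if (h %% heads != 0L)
      stop("assemble_yolo_ginseng: stage width ", gw(c),
           " gives split half ", h, ", not divisible by n_heads = ", heads)
  }
  assemble_graph(cfg, use_c3frn = TRUE)
}

# single-module forward dispatch
fw_module <- function(m, x, ctx) {
  switch(m$kind,
         conv_bn = fw_conv_bn(m, x, ctx),
         conv_bias = fw_conv_bias(m, x, ctx),
         c3 = fw_c3(m, x, ctx),
         c3frn = fw_c3frn(m, x, ctx),
         sppf = fw_sppf(m, x, ctx),
         sac = fw_sac(m, x, ctx),
         ca = fw_ca(m, x, ctx),
         bneck = fw_bneck(m, x, ctx),
         swin_stage = fw_swin_stage(m, x, ctx),
         stop("no forward for kind ", m$kind))
}

#' Run the detector graph.
#'
#' @param model a model from the assemblers, with initialised parameters
#' @param x input image batch, array `c(H, W, 3, N)`, values in `[0, 1]`
#' @param train logical; record gradients and use batch statistics
#' @return list of three raw prediction maps (strides 8/16/32), each
#'   `c(H/s, W/s, na*(nc+5), N)`; in train mode these are tape nodes
#' @export
forward_detector <- function(model, x, train = FALSE, bn_momentum = NULL) {
  ctx <- list(env = model$env, train = train, bn_momentum = bn_momentum)
  outs <- vector("list", length(model$layers))
  cur <- x
  for (i in seq_along(model$layers)) {
    entry <- model$layers[[i]]
    m <- entry$m
    if (identical(m$kind, "upsample")) {
      cur <- ag_upsample(cur, 2L)
    } else if (identical(m$kind, "concat")) {
      srcs <- lapply(entry$from, function(f) if (f == 0) cur else outs[[f]])
      cur <- ag_concat(srcs, 3L)
    } else if (identical(m$kind, "detect")) {
      srcs <- lapply(entry$from, function(f) outs[[f]])
      preds <- lapply(seq_along(srcs), function(k)
        fw_conv_bias(m$convs[[k]], srcs[[k]], ctx))
      outs[[i]] <- preds
      cur <- preds
    } else {
      src <- if (entry$from[1] == 0) cur else outs[[entry$from[1]]]
      if (anyNA(vof(src))) stop("forward_detector: NaN activations entering layer ", i)
      cur <- fw_module(m, src, ctx)
    }
    outs[[i]] <- cur
  }
  outs[[length(model$layers)]]
}

#' Recompute BN running statistics from data (precise-BN refresh).
#'
#' Short training schedules leave the exponential running statistics far
#' behind the batch statistics the network was actually trained with, which
#' cripples evaluation-mode forward passes. This pass replaces them with the
#' cumulative average of batch statistics over a few batches.
#' @param model an initialised model
#' @param items labelled scenes to draw batches from
#' @param batch_size images per refresh batch
#' @param n_batches number of batches to average
#' @return the model, invisibly
#' @export
refresh_bn_stats <- function(model, items, batch_size = 8L, n_batches = 2L) {
  n_batches <- min(n_batches, max(1L, length(items) %/% batch_size))
  for (i in seq_len(n_batches)) {
    idx <- ((i - 1L) * batch_size + 1L):min(i * batch_size, length(items))
    batch <- make_batch(items[idx], model$cfg$img_size)
    invisible(forward_detector(model, batch$x, train = TRUE, bn_momentum = 1 / i))
  }
  invisible(model)
}

# ---- FLOP accounting -------------------------------------------------------

conv_macs <- function(k, c1, c2, H, W, s = 1L) {
  (k * k * c1 * c2) * ceiling(H / s) * ceiling(W / s)
}

macs_module <- function(m, H, W) {
  switch(m$kind,
    conv_bn = list(macs = conv_macs(m$k, m$c1, m$c2, H, W, m$s),
                   H = ceiling(H / m$s), W = ceiling(W / m$s)),
    conv_bias = list(macs = conv_macs(m$k, m$c1, m$c2, H, W, m$s),
                     H = ceiling(H / m$s), W = ceiling(W / m$s)),
    c3 = {
      mm <- conv_macs(1, m$c1, m$c_, H, W) * 2 + conv_macs(1, 2 * m$c_, m$c2, H, W)
      for (bn in m$m) mm <- mm + conv_macs(1, m$c_, m$c_, H, W) + conv_macs(3, m$c_, m$c_, H, W)
      list(macs = mm, H = H, W = W)
    },
    sppf = list(macs = conv_macs(1, m$c1, m$c_, H, W) + conv_macs(1, 4 * m$c_, m$c2, H, W),
                H = H, W = W),
    c3frn = {
      h <- m$h; c1 <- m$c1; c2 <- m$c2; n <- m$n
      mm <- 2 * conv_macs(1, c1, 2 * h, H, W)                   # the two branch stems
      mm <- mm + (n + 1) * 2 * conv_macs(3, h, h, H, W)         # bottlenecks
      mm <- mm + conv_macs(3, h, h, H, W)                       # pre-attention conv
      ps <- m$swin$ps; Hp <- ceiling(H / ps); Wp <- ceiling(W / ps)
      d <- m$swin$d
      mm <- mm + conv_macs(ps, h, d, H, W, ps)                  # patch embedding
      nblk <- length(m$swin$blocks)
      mm <- mm + nblk * (conv_macs(1, d, 3 * d, Hp, Wp) + conv_macs(1, d, d, Hp, Wp) +
                         conv_macs(1, d, 4 * d, Hp, Wp) + conv_macs(1, 4 * d, d, Hp, Wp))
      mm <- mm + conv_macs(1, (2 + n) * h, c2, H, W) + conv_macs(1, 3 * h, c2, H, W)
      mm <- mm + 2 * conv_macs(1, c2, c2, H, W)                 # projections
      mm <- mm + 2 * conv_macs(3, c2, c2, H, W) + conv_macs(1, c2, 1, H, W)  # SAC
      mip <- m$ca$mip
      mm <- mm + (H + W) * c2 * mip + H * mip * c2 + W * mip * c2            # CA strips
      list(macs = mm, H = H, W = W)
    },
    stop("macs_module: unhandled kind ", m$kind))
}

#' Count multiply-accumulate load of a model.
#'
#' Convention: multiply-accumulate operations of convolution and linear
#' (1x1-convolution) layers only, times two, at the given input resolution;
#' attention score products, normalisations and activations are excluded.
#' @param model a built model
#' @param img_size input resolution (divisible by 32)
#' @return GFLOPs (double)
#' @export
count_flops <- function(model, img_size = NULL) {
  cfg <- model$cfg
  img <- img_size %||% cfg$img_size
  if (img %% 32L != 0L) stop("count_flops: img_size must be divisible by 32")
  H <- img; W <- img
  total <- 0
  sizes <- list()
  for (i in seq_along(model$layers)) {
    entry <- model$layers[[i]]
    m <- entry$m
    if (identical(m$kind, "upsample")) {
      src <- sizes[[i - 1L]]
      sizes[[i]] <- list(H = src$H * 2L, W = src$W * 2L)
    } else if (identical(m$kind, "concat")) {
      f <- entry$from[1]
      sizes[[i]] <- sizes[[if (f == 0) i - 1L else f]]
    } else if (identical(m$kind, "detect")) {
      for (k in seq_along(entry$from)) {
        src <- sizes[[entry$from[k]]]
        cv <- m$convs[[k]]
        total <- total + conv_macs(1, cv$c1, cv$c2, src$H, src$W)
      }
      sizes[[i]] <- sizes[[i - 1L]]
    } else {
      src <- if (entry$from[1] == 0) {
        if (i == 1L) list(H = H, W = W) else sizes[[i - 1L]]
      } else sizes[[entry$from[1]]]
      r <- macs_module(m, src$H, src$W)
      total <- total + r$macs
      sizes[[i]] <- list(H = r$H, W = r$W)
    }
  }
  2 * total / 1e9
}
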