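# C3f-RN: dual CSP-style branches with SimAM-tailed bottlenecks, a windowed
# attention stage on one split half, merged through 1x1 projections, then
# switchable atrous convolution and coordinate attention.

#' C3f-RN module configuration.
#'
#' @param c_in,c_out channel counts (equal when the module replaces a
#'   same-width stage)
#' @param n_repeats bottleneck count of branch one, inherited from the host
#'   stage; branch two always carries a single bottleneck beside its
#'   attention path
#' @param swin a [swin_config()]; its `embed_dim` defaults to the split-half
#'   width `c_out / 2`
#' @return an object of class `c3frn_config`
#' @export
c3f_rn_config <- function(c_in, c_out = c_in, n_repeats = 1L,
                          swin = swin_config()) {
  if (c_in <= 0L || c_out <= 0L) stop("c3f_rn_config: channel counts must be positive")
  if (c_out %% 2L != 0L) stop("c3f_rn_config: c_out must be even (split halves)")
  structure(list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                 n_repeats = as.integer(n_repeats), swin = swin),
            class = "c3frn_config")
}

# bottleneck: two 3x3 conv+BN+SiLU at width h, SimAM tail, optional shortcut
mk_bneck <- function(env, id, h, residual = TRUE, simam_tail = TRUE) {
  list(kind = "bneck", id = id, h = h, residual = residual, simam_tail = simam_tail,
       cv1 = mk_conv_bn(env, paste0(id, ".cv1"), h, h, 3L),
       cv2 = mk_conv_bn(env, paste0(id, ".cv2"), h, h, 3L))
}

fw_bneck <- function(m, x, ctx) {
  y <- fw_conv_bn(m$cv2, fw_conv_bn(m$cv1, x, ctx), ctx)
  if (m$simam_tail) y <- simam(y)
  if (m$residual) ag_add(x, y) else y
}

mk_c3frn <- function(env, id, cfg) {
  c1 <- cfg$c_in; c2 <- cfg$c_out; h <- c2 %/% 2L; n <- cfg$n_repeats
  sw <- cfg$swin
  if (is.null(sw$embed_dim)) sw$embed_dim <- h
  if (sw$embed_dim %% sw$n_heads != 0L)
    stop("c3f_rn: split-half width ", sw$embed_dim,
         " is not divisible by n_heads = ", sw$n_heads)
  list(kind = "c3frn", id = id, c1 = c1, c2 = c2, h = h, n = n,
       cv1a = mk_conv_bn(env, paste0(id, ".b1.cv1"), c1, 2L * h, 1L),
       m1 = lapply(seq_len(n), function(i)
         mk_bneck(env, paste0(id, ".b1.m", i), h, residual = TRUE)),
       cv2a = mk_conv_bn(env, paste0(id, ".b1.cv2"), (2L + n) * h, c2, 1L),
       cv1b = mk_conv_bn(env, paste0(id, ".b2.cv1"), c1, 2L * h, 1L),
       # branch two: interleaving starts with a residual bottleneck
       m2 = list(mk_bneck(env, paste0(id, ".b2.m1"), h, residual = TRUE)),
       pre3 = mk_conv_bn(env, paste0(id, ".b2.pre"), h, h, 3L),
       swin = mk_swin_stage(env, paste0(id, ".b2.swin"), h, sw),
       cv2b = mk_conv_bn(env, paste0(id, ".b2.cv2"), 3L * h, c2, 1L),
       proj1 = mk_conv_bn(env, paste0(id, ".proj1"), c2, c2, 1L),
       proj2 = mk_conv_bn(env, paste0(id, ".proj2"), c2, c2, 1L),
       sac = mk_sac(env, paste0(id, ".sac"), c2, c2),
       ca = mk_ca(env, paste0(id, ".ca"), c2))
}

fw_branch_one <- function(m, x, ctx) {
  t <- fw_conv_bn(m$cv1a, x, ctx)
  h <- m$h
  parts <- list(ag_slice(t, 3L, 1:h), ag_slice(t, 3L, (h + 1L):(2L * h)))
  cur <- parts[[2]]
  for (bn in m$m1) {
    cur <- fw_bneck(bn, cur, ctx)
    parts[[length(parts) + 1L]] <- cur
  }
  fw_conv_bn(m$cv2a, ag_concat(parts, 3L), ctx)
}

fw_branch_two <- function(m, x, ctx) {
  t <- fw_conv_bn(m$cv1b, x, ctx)
  h <- m$h
  z1 <- ag_slice(t, 3L, 1:h); z2 <- ag_slice(t, 3L, (h + 1L):(2L * h))
  parts <- list(z1)
  cur <- z1
  for (bn in m$m2) {
    cur <- fw_bneck(bn, cur, ctx)
    parts[[length(parts) + 1L]] <- cur
  }
  s <- fw_swin_stage(m$swin, fw_conv_bn(m$pre3, z2, ctx), ctx)
  parts[[length(parts) + 1L]] <- s
  fw_conv_bn(m$cv2b, ag_concat(parts, 3L), ctx)
}

fw_c3frn <- function(m, x, ctx) {
  b1 <- fw_conv_bn(m$proj1, fw_branch_one(m, x, ctx), ctx)
  b2 <- fw_conv_bn(m$proj2, fw_branch_two(m, x, ctx), ctx)
  y <- fw_sac(m$sac, ag_add(b1, b2), ctx)
  fw_ca(m$ca, y, ctx)
}

#' Run a C3f-RN module on a feature map.
#'
#' Builds (or reuses) a module with the given configuration and applies it.
#' The output has `c_out` channels and the input's spatial extent, making
#' the module insertable wherever a same-shape block is expected.
#'
#' @param x feature map `c(H, W, C, N)` with `C = cfg$c_in`
#' @param cfg a [c3f_rn_config()]
#' @param layer optional prebuilt module
#' @param seed seed for throwaway weights when no layer is given
#' @return feature map `c(H, W, c_out, N)`
#' @export
c3f_rn_forward <- function(x, cfg, layer = NULL, seed = 0L) {
  if (dim(x)[3] != cfg$c_in) stop("c3f_rn_forward: input has wrong channel count")
  if (is.null(layer))
    layer <- standalone_module(function(env) mk_c3frn(env, "c3frn", cfg), seed)
  vof(fw_c3frn(layer$m, x, layer$ctx))
}

#' Branch one of C3f-RN (residual bottleneck branch).
#' @inheritParams c3f_rn_forward
#' @return feature map with `c_out` channels
#' @export
branch_one <- function(x, cfg, layer = NULL, seed = 0L) {
  if (is.null(layer))
    layer <- standalone_module(function(env) mk_c3frn(env, "c3frn", cfg), seed)
  vof(fw_branch_one(layer$m, x, layer$ctx))
}

#' Branch two of C3f-RN (bottleneck plus windowed-attention branch).
#' @inheritParams c3f_rn_forward
#' @return feature map with `c_out` channels
#' @export
branch_two <- function(x, cfg, layer = NULL, seed = 0L) {
  if (is.null(layer))
    layer <- standalone_module(function(env) mk_c3frn(env, "c3frn", cfg), seed)
  vof(fw_branch_two(layer$m, x, layer$ctx))
}

#' A single C3f-RN bottleneck (two 3x3 convolutions with SimAM tail).
#'
#' @param x feature map whose channel count matches `channels`
#' @param channels working width
#' @param residual add the identity shortcut (requires matching channels)
#' @param simam_tail apply the parameter-free SimAM gate at the end
#' @param layer optional prebuilt layer
#' @param seed seed for throwaway weights
#' @return feature map, same shape as `x`
#' @export
bottleneck <- function(x, channels, residual = TRUE, simam_tail = TRUE,
                       layer = NULL, seed = 0L) {
  if (residual && dim(x)[3] != channels)
    stop("bottleneck: residual shortcut requires matching channel counts")
  if (is.null(layer))
    layer <- standalone_module(function(env)
      mk_bneck(env, "bneck", channels, residual, simam_tail), seed)
  vof(fw_bneck(layer$m, x, layer$ctx))
}
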