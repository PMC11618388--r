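# Module system: modules are nested lists of cfg + parameter ids; a model
# environment owns the parameter arrays. Parameter shapes are registered at
# build time so exact counting never materialises weights.

new_model_env <- function() {
  m <- new.env(parent = emptyenv())
  m$shapes <- new.env(parent = emptyenv())   # pid -> dim vector
  m$params <- new.env(parent = emptyenv())   # pid -> array (lazy)
  m$grads  <- new.env(parent = emptyenv())
  m$buffers <- new.env(parent = emptyenv())  # running BN stats
  m$meta <- new.env(parent = emptyenv())     # pid -> list(kind=...)
  m
}

reg_param <- function(env, pid, shape, kind = "weight") {
  env$shapes[[pid]] <- as.integer(shape)
  env$meta[[pid]] <- list(kind = kind)
  pid
}

# ---- initialisation -------------------------------------------------------

#' Materialise model weights.
#'
#' Kaiming-uniform fan-in initialisation for convolution and linear kernels,
#' ones/zeros for normalisation scales and biases, zeros for structurally
#' zero-initialised tensors (SAC weight offsets, switch weights).
#' @param model a model built by [assemble_baseline()], [assemble_yolo_ginseng()]
#'   or a toy-net constructor
#' @param seed integer seed making the initialisation reproducible
#' @return the model, invisibly (weights are stored in the model environment)
#' @export
init_parameters <- function(model, seed = 0L) {
  env <- model$env
  set.seed(seed)
  for (pid in ls(env$shapes)) {
    shape <- env$shapes[[pid]]
    kind <- env$meta[[pid]]$kind
    env$params[[pid]] <- switch(kind,
      weight = {
        fan_in <- if (length(shape) == 4L) prod(shape[1:3]) else shape[1]
        bound <- sqrt(6 / fan_in) # kaiming uniform, a = sqrt(5) gain folded
        array(stats::runif(prod(shape), -bound, bound), dim = shape)
      },
      ones  = array(1, dim = shape),
      zeros = array(0, dim = shape),
      switch_bias = array(1, dim = shape),  # SAC switch starts fully on branch 1
      array(0, dim = shape))
  }
  rm(list = ls(env$grads), envir = env$grads)  # assigning NULL would bind NULL
  for (pid in ls(env$shapes)) {
    if (grepl("\\.bn_g$", pid)) {
      base <- sub("\\.bn_g$", "", pid)
      env$buffers[[paste0(base, ".bn_m")]] <- array(0, dim = env$shapes[[pid]])
      env$buffers[[paste0(base, ".bn_v")]] <- array(1, dim = env$shapes[[pid]])
    }
  }
  init_detect_biases(model)
  invisible(model)
}

# Prior-aware detection-head bias initialisation: the objectness bias starts
# at the log-odds of ~8 objects per image at each scale and the class bias
# strongly positive, so early training does not collapse the objectness.
init_detect_biases <- function(model) {
  if (is.null(model$layers)) return(invisible(model))
  env <- model$env
  img <- model$cfg$img_size
  for (entry in model$layers) {
    m <- entry$m
    if (!identical(m$kind, "detect")) next
    nc <- m$nc; no <- m$no; na <- m$na
    for (k in seq_along(m$convs)) {
      stride <- model$strides[k]
      bid <- paste0(m$convs[[k]]$id, ".b")
      if (is.null(env$params[[bid]])) next
      b <- env$params[[bid]]
      for (a in seq_len(na)) {
        b0 <- (a - 1L) * no
        b[b0 + 5L] <- log(8 / (img / stride)^2)
        b[b0 + 5L + seq_len(nc)] <- log(0.6 / max(nc - 0.99, 0.01))
      }
      env$params[[bid]] <- b
    }
  }
  invisible(model)
}

pget <- function(ctx, pid) {
  v <- ctx$env$params[[pid]]
  if (is.null(v)) stop("parameter not initialised: ", pid, " (call init_parameters)")
  if (isTRUE(ctx$train)) ag_leaf(v, pid = pid) else v
}

# ---- elementary layer constructors ----------------------------------------

# conv (no bias) + BatchNorm + activation, the CSP-family workhorse
mk_conv_bn <- function(env, id, c1, c2, k = 1L, s = 1L, act = "silu", d = 1L) {
  list(kind = "conv_bn", id = id, c1 = c1, c2 = c2, k = k, s = s, d = d, act = act,
       w = reg_param(env, paste0(id, ".w"), c(k, k, c1, c2), "weight"),
       g = reg_param(env, paste0(id, ".bn_g"), c2, "ones"),
       b = reg_param(env, paste0(id, ".bn_b"), c2, "zeros"))
}

mk_conv_bias <- function(env, id, c1, c2, k = 1L, s = 1L, wkind = "weight", bkind = "zeros") {
  list(kind = "conv_bias", id = id, c1 = c1, c2 = c2, k = k, s = s,
       w = reg_param(env, paste0(id, ".w"), c(k, k, c1, c2), wkind),
       b = reg_param(env, paste0(id, ".b"), c2, bkind))
}

mk_layernorm <- function(env, id, c) {
  list(kind = "layernorm", id = id, c = c,
       g = reg_param(env, paste0(id, ".ln_g"), c, "ones"),
       b = reg_param(env, paste0(id, ".ln_b"), c, "zeros"))
}

fw_conv_bn <- function(m, x, ctx) {
  pad <- if (m$k > 1L) (m$d * (m$k - 1L)) %/% 2L else 0L
  y <- ag_conv(x, pget(ctx, m$w), NULL, stride = m$s, pad = pad, dil = m$d)
  y <- fw_bn(m, y, ctx)
  switch(m$act, silu = ag_silu(y), hswish = ag_hswish(y), none = y)
}

fw_bn <- function(m, y, ctx) {
  env <- ctx$env
  gamma <- pget(ctx, m$g); beta <- pget(ctx, m$b)
  base <- sub("\\.bn_g$", "", m$g)
  mkey <- paste0(base, ".bn_m"); vkey <- paste0(base, ".bn_v")
  if (isTRUE(ctx$train)) {
    r <- ag_bn_train(y, gamma, beta)
    mom <- ctx$bn_momentum %||% 0.03
    env$buffers[[mkey]] <- (1 - mom) * env$buffers[[mkey]] + mom * r$stats$mean
    env$buffers[[vkey]] <- (1 - mom) * env$buffers[[vkey]] + mom * r$stats$var
    r$out
  } else {
    ag_bn_eval(y, gamma, beta, env$buffers[[mkey]], env$buffers[[vkey]])
  }
}

fw_conv_bias <- function(m, x, ctx, pad = NULL, dil = 1L, w_override = NULL) {
  if (is.null(pad)) pad <- if (m$k > 1L) (dil * (m$k - 1L)) %/% 2L else 0L
  w <- if (is.null(w_override)) pget(ctx, m$w) else w_override
  ag_conv(x, w, pget(ctx, m$b), stride = m$s, pad = pad, dil = dil)
}

# ---- parameter accounting -------------------------------------------------

count_pids <- function(env, fuse_bn = FALSE) {
  total <- 0
  for (pid in ls(env$shapes)) {
    n <- prod(env$shapes[[pid]])
    if (fuse_bn) {
      if (grepl("\\.bn_g$", pid)) next            # gamma folds into the kernel
      if (grepl("\\.bn_b$", pid)) n <- n          # beta becomes the conv bias
    }
    total <- total + n
  }
  total
}

#' Count learnable parameters of a model.
#'
#' With `fuse_bn = TRUE` the count reflects the deployed model in which every
#' convolution-batchnorm pair has been folded into a biased convolution
#' (gamma disappears into the kernel, beta becomes the bias), the convention
#' used by detector validation tools when they report a "fused" summary.
#' @param model a built model
#' @param fuse_bn logical; report the BN-fused (deploy-time) count
#' @return integer parameter count
#' @export
count_parameters <- function(model, fuse_bn = FALSE) {
  count_pids(model$env, fuse_bn = fuse_bn)
}
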