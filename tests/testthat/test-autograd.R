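# Reverse-mode correctness: every operator's analytic gradient is checked
# against central differences on small random tensors.

ns <- asNamespace("yologinseng")

# strict double-precision convolutions for finite-difference comparisons
old_opt <- options(yologinseng.conv_double = TRUE)
withr::defer(options(old_opt), teardown_env())

test_that("convolution gradients match central differences", {
  set.seed(1)
  cases <- list(list(k = 3L, s = 1L, p = 1L, d = 1L),
                list(k = 3L, s = 2L, p = 1L, d = 1L),
                list(k = 1L, s = 1L, p = 0L, d = 1L),   # pointwise fast path
                list(k = 3L, s = 1L, p = 3L, d = 3L))   # atrous
  for (cs in cases) {
    x <- rand_map(5, 6, 3, 2, seed = cs$k + cs$s)
    w <- array(rnorm(cs$k^2 * 3 * 4) * 0.3, c(cs$k, cs$k, 3, 4))
    b <- rnorm(4) * 0.1
    gc <- ns$ag_gradcheck(function(a)
      ns$ag_sum(ns$ag_sq(ns$ag_conv(a[[1]], a[[2]], a[[3]],
                                    stride = cs$s, pad = cs$p, dil = cs$d))),
      list(x, w, b))
    expect_lt(max_rel_err(gc), 1e-6)
  }
})

test_that("normalisation gradients match central differences", {
  set.seed(2)
  x <- rand_map(4, 4, 3, 2, seed = 7)
  g <- rnorm(3) * 0.5 + 1; b <- rnorm(3) * 0.2
  gc <- ns$ag_gradcheck(function(a)
    ns$ag_sum(ns$ag_sq(ns$ag_bn_train(a[[1]], a[[2]], a[[3]])$out)), list(x, g, b))
  expect_lt(max_rel_err(gc), 1e-4)

  rm_ <- rnorm(3) * 0.1; rv_ <- abs(rnorm(3)) + 0.5
  gc2 <- ns$ag_gradcheck(function(a)
    ns$ag_sum(ns$ag_sq(ns$ag_bn_eval(a[[1]], a[[2]], a[[3]], rm_, rv_))), list(x, g, b))
  expect_lt(max_rel_err(gc2), 1e-6)

  x6 <- rand_map(3, 2, 6, 2, seed = 8)
  g6 <- rnorm(6) * 0.3 + 1; b6 <- rnorm(6) * 0.3
  gc3 <- ns$ag_gradcheck(function(a)
    ns$ag_sum(ns$ag_sq(ns$ag_layernorm_c(a[[1]], a[[2]], a[[3]]))), list(x6, g6, b6))
  expect_lt(max_rel_err(gc3), 1e-6)

  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  wg <- rnorm(3) * 0.2 + 1; wb <- rnorm(3) * 0.2
  gc4 <- ns$ag_gradcheck(function(a)
    ns$ag_sum(ns$ag_sq(ns$ag_aws_weight(a[[1]], a[[2]], a[[3]]))), list(w, wg, wb))
  expect_lt(max_rel_err(gc4), 1e-4)
})

test_that("windowed attention gradients cover shift, padding and bias table", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 6) * 0.5, c(5, 5, 6, 1))   # 5 not divisible by 4
  rb <- array(rnorm(2 * 49) * 0.1, c(2, 49))
  for (shift in c(0L, 2L)) {
    gc <- ns$ag_gradcheck(function(a)
      ns$ag_sum(ns$ag_sq(ns$ag_window_attention(a[[1]], a[[2]], 2L, 2L, 4L, shift))),
      list(x, rb))
    expect_lt(max_rel_err(gc), 1e-6)
  }
})

test_that("elementwise, pooling and shape operators back-propagate exactly", {
  set.seed(4)
  x <- rand_map(6, 6, 2, 1, seed = 5)
  unary <- list(
    silu = function(a) ns$ag_silu(a[[1]]),
    sigmoid = function(a) ns$ag_sigmoid(a[[1]]),
    gelu = function(a) ns$ag_gelu(a[[1]]),
    hswish = function(a) ns$ag_hswish(a[[1]]),
    atan = function(a) ns$ag_atan(a[[1]]),
    maxpool = function(a) ns$ag_maxpool(a[[1]], 3L),
    upsample = function(a) ns$ag_upsample(a[[1]], 2L),
    avgpool = function(a) ns$ag_avgpool_same(a[[1]], 5L),
    pool_w = function(a) ns$ag_pool_w(a[[1]]),
    pool_h = function(a) ns$ag_pool_h(a[[1]]),
    simam = function(a) simam(a[[1]]),
    slice = function(a) ns$ag_slice(a[[1]], 3L, 2L))
  for (nm in names(unary)) {
    gc <- ns$ag_gradcheck(function(a) ns$ag_sum(ns$ag_sq(unary[[nm]](a))), list(x))
    expect_lt(max_rel_err(gc), 1e-5)
  }
  x2 <- rand_map(6, 6, 3, 1, seed = 6)
  gc <- ns$ag_gradcheck(function(a)
    ns$ag_sum(ns$ag_sq(ns$ag_concat(list(a[[1]], a[[2]]), 3L))), list(x, x2))
  expect_lt(max_rel_err(gc), 1e-6)
  s <- rand_map(6, 6, 1, 1, seed = 7)
  gc2 <- ns$ag_gradcheck(function(a)
    ns$ag_sum(ns$ag_sq(ns$ag_mul_bc(a[[1]], a[[2]]))), list(x, s))
  expect_lt(max_rel_err(gc2), 1e-6)
})

test_that("a full C3f-RN module back-propagates into every parameter", {
  cfg <- tiny_c3frn_cfg()
  sa <- ns$standalone_module(function(env) ns$mk_c3frn(env, "m", cfg), seed = 3)
  env <- sa$model$env
  ctx <- list(env = env, train = TRUE)
  x <- rand_map(6, 6, 8, 2, seed = 11, scale = 0.5)
  lossfun <- function() ns$ag_sum(ns$ag_sq(ns$fw_c3frn(sa$m, ns$ag_leaf(x), ctx)))
  ns$ag_backward(lossfun(), env$grads)
  pids <- ls(env$grads)
  expect_setequal(pids, ls(env$shapes))
  # numeric spot-checks across structurally different parameters
  eps <- 1e-5
  for (pid in c(grep("sac.w$", pids, value = TRUE),
                grep("relbias", pids, value = TRUE)[1],
                grep("qkv.w", pids, value = TRUE)[1],
                grep("ca.cvh.w", pids, value = TRUE))) {
    i <- min(2L, length(env$params[[pid]]))
    g_an <- env$grads[[pid]][i]
    bufs <- as.list(env$buffers)
    p0 <- env$params[[pid]][i]
    env$params[[pid]][i] <- p0 + eps; lp <- ns$vof(lossfun())
    env$params[[pid]][i] <- p0 - eps; lm <- ns$vof(lossfun())
    env$params[[pid]][i] <- p0
    for (nm in names(bufs)) env$buffers[[nm]] <- bufs[[nm]]
    expect_lt(abs(g_an - (lp - lm) / (2 * eps)) / max(1e-6, abs(g_an)), 1e-4)
  }
})
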