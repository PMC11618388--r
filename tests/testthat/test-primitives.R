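# The reusable operators: BN transform, SimAM, coordinate attention, SAC,
# window partitioning and the Swin stage.

test_that("bn_forward implements the per-channel affine normalisation", {
  # hand arithmetic: x=3, mu=1, sigma^2=3.99, eps=0.01, gamma=2, beta=0.5
  x <- array(3, c(1, 1, 1, 1))
  st <- list(gamma = 2, beta = 0.5, mean = 1, sd = sqrt(3.99), eps = 0.01)
  expect_equal(as.numeric(bn_forward(x, st)), 2.5)

  # x equal to the mean everywhere -> output is beta per channel
  x2 <- array(rep(c(1, -2), each = 12), c(3, 4, 2, 1))
  st2 <- list(gamma = c(3, 4), beta = c(0.25, -1), mean = c(1, -2),
              sd = c(0.5, 2), eps = 1e-5)
  y2 <- bn_forward(x2, st2)
  expect_equal(as.numeric(y2[, , 1, 1]), rep(0.25, 12))
  expect_equal(as.numeric(y2[, , 2, 1]), rep(-1, 12))

  # gamma = 0 annihilates the input
  st3 <- st2; st3$gamma <- c(0, 0)
  y3 <- bn_forward(rand_map(3, 4, 2, 1), st3)
  expect_equal(as.numeric(y3[, , 1, 1]), rep(0.25, 12))

  expect_error(bn_forward(rand_map(2, 2, 3, 1), st2), "channel")
  expect_error(bn_forward(x2, modifyList(st2, list(eps = 0))), "eps")
})

test_that("simam gates preserve shape, stay in (0,1) and spot outliers", {
  x <- rand_map(5, 7, 3, 2, seed = 11)
  y <- simam(x)
  expect_identical(dim(y), dim(x))
  g <- y / ifelse(abs(x) < 1e-12, 1, x)
  expect_true(all(g[abs(x) >= 1e-12] > 0 & g[abs(x) >= 1e-12] < 1))

  # constant channel -> uniform gate
  xc <- array(2.5, c(4, 4, 1, 1))
  yc <- simam(xc)
  expect_equal(max(yc) - min(yc), 0)

  # 2x2 channel [1,1,1,5]: gate maximal at the outlier
  # (independent evaluation of the energy formula: d=(x-mu)^2, mu=2,
  #  v=sum(d)/3=4, gate=sigmoid(d/(4(v+1e-4))+0.5))
  xo <- array(c(1, 1, 1, 5), c(2, 2, 1, 1))
  d <- (c(1, 1, 1, 5) - 2)^2
  v <- sum(d) / 3
  expected <- c(1, 1, 1, 5) * stats::plogis(d / (4 * (v + 1e-4)) + 0.5)
  expect_equal(as.numeric(simam(xo)), expected, tolerance = 1e-12)
  expect_gt(simam(xo)[2, 2, 1, 1] / 5, max(simam(xo)[1:2, 1, 1, 1]))

  expect_error(simam(array(1, c(1, 1, 2, 1))), "2 spatial")
})

test_that("simam adds zero learnable parameters inside a bottleneck", {
  env1 <- yologinseng:::new_model_env()
  yologinseng:::mk_bneck(env1, "b", 8L, simam_tail = TRUE)
  env2 <- yologinseng:::new_model_env()
  yologinseng:::mk_bneck(env2, "b", 8L, simam_tail = FALSE)
  expect_identical(yologinseng:::count_pids(env1), yologinseng:::count_pids(env2))
  # and the closed form: two 3x3 conv+BN at width h
  h <- 8
  expect_identical(yologinseng:::count_pids(env1), 2 * (9 * h * h + 2 * h))
})

test_that("coordinate attention keeps shape and reduces to gates in (0,1)", {
  x <- rand_map(6, 5, 16, 2, seed = 3)
  y <- coordinate_attention(x, reduction = 4L, seed = 1)
  expect_identical(dim(y), dim(x))

  # constant input per channel: the two directional gates are constant, so
  # the output is constant per channel too
  xc <- array(rep(c(1, -1), each = 30), c(5, 6, 2, 1))
  yc <- coordinate_attention(xc, reduction = 2L, seed = 2)
  expect_lt(max(abs(yc[, , 1, 1] - yc[1, 1, 1, 1])), 1e-12)

  # intermediate width is clamped to at least 8
  env <- yologinseng:::new_model_env()
  ca <- yologinseng:::mk_ca(env, "ca", 16L, reduction = 32L)
  expect_identical(ca$mip, 8L)
})

test_that("switchable atrous convolution is the rate-1 branch at init", {
  # the switch head initialises to 1 (weights 0, bias 1), so a fresh layer
  # must reproduce a plain rate-1 convolution with the standardised kernel
  withr::local_options(yologinseng.conv_double = TRUE)
  x <- rand_map(7, 7, 4, 1, seed = 9)
  sa <- yologinseng:::standalone_module(function(env)
    yologinseng:::mk_sac(env, "sac", 4L, 4L), seed = 4)
  y <- switchable_atrous_conv(x, layer = sa)
  env <- sa$model$env
  w_std <- yologinseng:::vof(yologinseng:::ag_aws_weight(
    env$params[["sac.w"]], env$params[["sac.aws_g"]], env$params[["sac.aws_b"]]))
  sw <- 1 / (1 + exp(-1))  # sigmoid of the switch bias
  y1 <- yologinseng:::cpp_conv2d(x, dim(x), w_std, dim(w_std),
                                 as.numeric(env$params[["sac.b"]]), 1L, 1L, 1L)
  y2 <- yologinseng:::cpp_conv2d(x, dim(x), w_std + env$params[["sac.wdiff"]],
                                 dim(w_std), as.numeric(env$params[["sac.b"]]),
                                 1L, 3L, 3L)
  expect_equal(y, sw * y1 + (1 - sw) * y2, tolerance = 1e-12)
  # weight_diff starts at zero, so both branches share the kernel and the
  # blend is rate-independent only where the dilated receptive fields agree
  expect_identical(dim(y), dim(x))
  expect_warning(yologinseng:::standalone_module(function(env)
    yologinseng:::mk_sac(env, "s", 4L, 4L, rates = c(2L, 2L))), "degenerate")
})

test_that("window partition counts windows per the area law and inverts", {
  x <- rand_map(4, 4, 3, 1)
  w <- window_partition(x, 4L)
  expect_identical(dim(w)[3], 1L)

  x2 <- rand_map(32, 32, 2, 1)
  w2 <- window_partition(x2, 4L)
  expect_identical(dim(w2)[3], 64L)          # 32*32 / 4^2
  expect_identical(num_windows(32, 32, 4), 64)

  # partition then reverse is exact, also on non-divisible extents
  for (side in c(32L, 30L, 7L)) {
    xs <- rand_map(side, side, 3, 2, seed = side)
    expect_identical(window_reverse(window_partition(xs, 4L)), xs)
  }
  expect_error(window_partition(x, 0L), "positive")
})

test_that("swin stage preserves spatial extent and alternates shifts", {
  cfg <- swin_config(depth = 2L, n_heads = 2L, win_size = 2L, patch_size = 1L)
  x <- rand_map(6, 6, 4, 1, seed = 2)
  y <- swin_stage(x, cfg, seed = 1)
  expect_identical(dim(y), dim(x))

  # parity rule: first block unshifted, second shifted by ws/2
  env <- yologinseng:::new_model_env()
  st <- yologinseng:::mk_swin_stage(env, "s", 4L, swin_config(depth = 4L, n_heads = 2L, win_size = 4L))
  expect_identical(vapply(st$blocks, function(b) b$shift, integer(1)), c(0L, 2L, 0L, 2L))

  expect_error(swin_config(depth = 3L), "even")
  expect_error(yologinseng:::mk_swin_stage(
    yologinseng:::new_model_env(), "s", 6L,
    swin_config(depth = 2L, n_heads = 4L, embed_dim = 6L)), "divisible")

  # window size 1: softmax over a single key is the identity weighting, so
  # attention output equals the value projection of each position
  cfg1 <- swin_config(depth = 2L, n_heads = 1L, win_size = 1L, patch_size = 1L)
  y1 <- swin_stage(rand_map(3, 3, 2, 1), cfg1, seed = 3)
  expect_identical(dim(y1), c(3L, 3L, 2L, 1L))

  # relative-position-bias budget: depth * n_heads * (2 ws - 1)^2 per stage
  env2 <- yologinseng:::new_model_env()
  yologinseng:::mk_swin_stage(env2, "s", 8L, swin_config(depth = 2L, n_heads = 2L, win_size = 4L))
  rb <- grep("relbias", ls(env2$shapes), value = TRUE)
  expect_identical(sum(vapply(rb, function(p) prod(env2$shapes[[p]]), numeric(1))),
                   2 * 2 * 49)
})

test_that("heads_from_window follows the square-root-of-window-count rule", {
  expect_identical(heads_from_window(32, 32, 4), 8L)   # 64 windows
  expect_identical(heads_from_window(7, 7, 7), 1L)     # single window
  expect_identical(heads_from_window(8, 8, 4), 2L)     # 4 windows
  # snapped to a divisor of the embedding width
  expect_identical(heads_from_window(32, 32, 4, embed_dim = 12L), 6L)
})
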