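# Slimming pipeline: sparsity subgradient, gamma summaries, thresholding,
# surgery exactness and conservation laws.

ns <- asNamespace("yologinseng")

test_that("sparse_step adds the L1 subgradient to BN scales only", {
  m <- toy_detector(widths = c(8L, 16L), img_size = 32L, strides_conf = c(2L, 2L))
  init_parameters(m, seed = 1)
  env <- m$env
  expect_error(sparse_step(m, 0.002), "not in a training step")
  # seed gradients, then check the exact increment lambda * sign(gamma)
  for (pid in ls(env$shapes)) env$grads[[pid]] <- array(0, dim = env$shapes[[pid]])
  env$params[["l0.bn_g"]][] <- c(0.5, -0.2, 0.3, -0.1, 0.2, 0.6, -0.4, 0.05)
  sparse_step(m, 0.002)
  expect_equal(as.numeric(env$grads[["l0.bn_g"]]),
               0.002 * sign(as.numeric(env$params[["l0.bn_g"]])))
  expect_equal(max(abs(env$grads[["l0.w"]])), 0)   # kernels untouched
  # single-scale hand update: gamma 0.5, no task gradient, lr 0.1, lambda 0.002
  g0 <- 0.5
  expect_equal(g0 - 0.1 * 0.002 * sign(g0), 0.4998)
})

test_that("gamma_summary conserves channels and matches hand quantiles", {
  m <- toy_detector(widths = c(8L, 8L), img_size = 32L, strides_conf = c(2L, 2L))
  init_parameters(m, seed = 2)
  s <- gamma_summary(m)
  expect_identical(s$n_channels, 16L)              # fresh init: all gammas 1
  expect_identical(as.numeric(s$abs_quantiles), rep(1, 5))
  known <- c(0.1, 0.4, 0.2, 0.9, 0.05, 0.3, 0.7, 0.6)
  m$env$params[["l0.bn_g"]][] <- known
  m$env$params[["l1.bn_g"]][] <- known
  s2 <- gamma_summary(m)
  expect_equal(s2$median_abs, stats::median(abs(rep(known, 2))))
  expect_identical(sum(s2$histogram$count), 16L)
})

test_that("prune threshold marks the expected channel fraction", {
  m <- toy_detector(widths = c(8L, 8L), img_size = 32L, strides_conf = c(2L, 2L))
  init_parameters(m, seed = 3)
  m$env$params[["l0.bn_g"]][] <- c(0.9, 0.5, 0.05, 0.01, 0.8, 0.85, 0.7, 0.95)
  m$env$params[["l1.bn_g"]][] <- c(0.12, 0.22, 0.33, 0.44, 0.55, 0.61, 0.73, 0.88)
  # r = 0: nothing marked
  thr0 <- prune_threshold(m, 0)
  expect_lte(thr0, 0.01)
  pool <- abs(c(m$env$params[["l0.bn_g"]], m$env$params[["l1.bn_g"]]))
  # marked fraction stays within 1/n of r before protection
  for (r in c(0.2, 0.5, 0.8)) {
    thr <- prune_threshold(m, r)
    frac <- mean(pool < thr)
    expect_lte(abs(frac - r), 1 / length(pool) + 1e-9)
  }
  expect_error(prune_threshold(m, 1), "r must be")
})

test_that("no-op pruning keeps the structure; surgery drops exact slices", {
  m <- toy_detector(widths = c(16L, 16L, 24L), img_size = 32L,
                    strides_conf = c(2L, 1L, 2L))
  init_parameters(m, seed = 4)
  p0 <- count_parameters(m)
  pr0 <- prune_channels(m, threshold = 0)   # below every |gamma| = 1
  expect_identical(count_parameters(pr0$model), p0)
  expect_identical(pr0$report$channels_removed, 0L)

  # remove one known mid-channel: parameter drop equals the hand count
  m$env$params[["l1.bn_g"]][5] <- 1e-6
  pr1 <- prune_channels(m, threshold = 1e-3)
  # losing one l1 output channel: its 3x3xC_in kernel slice + 2 BN scalars
  # + one 3x3 input slice in each l2 filter
  drop <- 3 * 3 * 16 + 2 + 3 * 3 * 24
  expect_identical(p0 - count_parameters(pr1$model), drop)
  expect_identical(pr1$report$channels_removed, 1L)
  expect_identical(pr1$report$layers_touched, 1L)
  # conservation per layer and in total
  rep_ <- pr1$report
  expect_identical(rep_$channels_removed + rep_$channels_kept, rep_$channels_before)
  expect_identical(rep_$per_layer$before - rep_$per_layer$removed, rep_$per_layer$kept)
})

test_that("pruning gamma=beta=0 channels leaves the function unchanged", {
  withr::local_options(yologinseng.conv_double = TRUE)  # bit-exact arithmetic
  m <- toy_detector(widths = c(16L, 16L, 32L, 32L), img_size = 64L,
                    strides_conf = c(2L, 1L, 2L, 2L))
  init_parameters(m, seed = 5)
  env <- m$env
  kill <- list(l1 = c(3L, 7L, 9L), l2 = c(1L, 20L))
  for (nm in names(kill)) {
    env$params[[paste0(nm, ".bn_g")]][kill[[nm]]] <- 0
    env$params[[paste0(nm, ".bn_b")]][kill[[nm]]] <- 0
  }
  x <- rand_map(64, 64, 3, 2, seed = 6, scale = 0.5) + 0.5
  y0 <- lapply(forward_detector(m, x), ns$vof)
  pr <- prune_channels(m, threshold = 1e-9, min_channels = 4L)
  expect_identical(pr$report$channels_removed, 5L)
  y1 <- lapply(forward_detector(pr$model, x), ns$vof)
  expect_equal(y1, y0, tolerance = 1e-12)
})

test_that("monotonicity: parameters after pruning are non-increasing in r", {
  m <- toy_detector(widths = c(16L, 16L, 24L), img_size = 32L,
                    strides_conf = c(2L, 1L, 2L))
  init_parameters(m, seed = 7)
  set.seed(8)
  for (pid in grep("bn_g$", ls(m$env$shapes), value = TRUE))
    m$env$params[[pid]][] <- runif(length(m$env$params[[pid]]), 0.01, 1)
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(r) {
    thr <- prune_threshold(m, r)
    count_parameters(prune_channels(m, thr, min_channels = 4L)$model)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("zero-epoch finetuning returns identical weights", {
  m <- toy_detector(widths = c(8L, 8L), img_size = 32L, strides_conf = c(2L, 2L))
  init_parameters(m, seed = 9)
  w0 <- as.list(m$env$params)
  r <- finetune(m, tiny_scene_set(2, img = 32L), epochs = 0L)
  expect_identical(as.list(r$model$env$params), w0)
})

test_that("composite detector graphs are guarded against surgery", {
  cfg <- model_config(nc = 1, width_mult = 0.125, img_size = 64L,
                      c3f_rn = list(depth = 2, n_heads = 2, win_size = 2))
  g <- assemble_yolo_ginseng(cfg)
  init_parameters(g, seed = 1)
  expect_error(prune_channels(g, 0.1), "protected")
  # but the sparsity signal and summaries cover it
  s <- gamma_summary(g)
  expect_gt(s$n_channels, 100L)
})
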