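# Network slimming: L1 sparsity on BN gamma, global-quantile channel
# pruning with graph surgery, and fine-tuning from the pruned weights.

#' Pruning pipeline configuration.
#'
#' @param lambda L1 sparsity rate on prunable BN scales (>= 0)
#' @param r pruning coefficient: fraction of channels removed network-wide,
#'   in `[0, 1)`
#' @param protected character vector of layer ids exempt from pruning
#' @param min_channels minimum channels retained per layer
#' @return object of class `prune_config`
#' @export
prune_config <- function(lambda = 0.002, r = 0.8, protected = character(0),
                         min_channels = 8L) {
  if (lambda < 0) stop("prune_config: lambda must be >= 0")
  if (r < 0 || r >= 1) stop("prune_config: r must be in [0, 1)")
  structure(list(lambda = lambda, r = r, protected = protected,
                 min_channels = as.integer(min_channels)),
            class = "prune_config")
}

prunable_gammas <- function(model, protected = character(0)) {
  env <- model$env
  pids <- grep("\\.bn_g$", ls(env$shapes), value = TRUE)
  if (length(protected))
    pids <- pids[!vapply(pids, function(p)
      any(startsWith(p, protected)), logical(1))]
  pids
}

#' L1 subgradient step on prunable BN scales.
#'
#' Adds `lambda * sign(gamma)` to the accumulated gradient of every
#' prunable BN gamma, the subgradient of `lambda * sum(|gamma|)`. Call
#' between the backward sweep and the optimiser step; [train_detector()]
#' does this when `sparsity_lambda > 0`.
#'
#' @param model a model whose gradients have just been computed
#' @param lambda sparsity rate
#' @param protected layer ids exempt from the penalty
#' @return invisibly, the number of penalised scale vectors
#' @export
sparse_step <- function(model, lambda, protected = character(0)) {
  env <- model$env
  if (!length(ls(env$grads)))
    stop("sparse_step: no gradients present; the model is not in a training step")
  pids <- prunable_gammas(model, protected)
  for (pid in pids) {
    g <- env$grads[[pid]]
    if (is.null(g)) next
    env$grads[[pid]] <- g + lambda * sign(env$params[[pid]])
  }
  invisible(length(pids))
}

#' Distribution summary of prunable BN scales.
#'
#' @param model an initialised model
#' @param protected layer ids to exclude
#' @param breaks histogram break count
#' @return list: `gammas` (named by layer), `abs_quantiles`, `median_abs`,
#'   `histogram` (data.frame of bin mids and counts), `n_channels`
#' @export
gamma_summary <- function(model, protected = character(0), breaks = 30L) {
  pids <- prunable_gammas(model, protected)
  if (!length(pids)) stop("gamma_summary: model has no prunable BN layers")
  vals <- unlist(lapply(pids, function(p) {
    v <- as.numeric(model$env$params[[p]])
    names(v) <- rep(sub("\\.bn_g$", "", p), length(v))
    v
  }))
  a <- abs(vals)
  h <- graphics::hist(a, breaks = breaks, plot = FALSE)
  list(gammas = vals,
       abs_quantiles = stats::quantile(a, c(0, 0.25, 0.5, 0.75, 1)),
       median_abs = stats::median(a),
       histogram = data.frame(mid = h$mids, count = h$counts),
       n_channels = length(vals))
}

#' Global pruning threshold from the pooled |gamma| distribution.
#'
#' @param model an initialised model
#' @param r pruning coefficient in `[0, 1)`; channels with `|gamma|`
#'   strictly below the r-quantile are marked for removal
#' @param protected layer ids to exclude from the pool
#' @return the threshold value
#' @export
prune_threshold <- function(model, r, protected = character(0)) {
  if (r < 0 || r >= 1) stop("prune_threshold: r must be in [0, 1)")
  pids <- prunable_gammas(model, protected)
  pool <- abs(unlist(lapply(pids, function(p) as.numeric(model$env$params[[p]]))))
  as.numeric(stats::quantile(pool, r))
}

# ---- channel surgery (sequential conv-BN chains) ---------------------------

# The surgeon operates on chain models: an ordered list of conv_bn layers in
# which layer i consumes layer i-1's full output, closed by a single-scale
# detection head. Coupled topologies (splits, residual sums, attention
# widths) are left to the protection policy.
is_chain_model <- function(model) identical(model$graph_kind, "chain")

#' Remove low-contribution channels and the filters that touch them.
#'
#' Marks channels whose `|gamma|` falls below `threshold`, retains at least
#' `min_channels` per layer (keeping the largest scales), and rebuilds the
#' network with sliced kernels, scales and running statistics so the pruned
#' graph is shape-consistent and forward-runnable. Supported on sequential
#' chain models (see [toy_detector()]); composite graphs must protect the
#' coupled layers.
#'
#' @param model a chain model with initialised parameters
#' @param threshold from [prune_threshold()]
#' @param protected layer ids exempt from pruning
#' @param min_channels minimum channels kept per layer
#' @return list: pruned `model` and `report` (class `prune_report`)
#' @export
prune_channels <- function(model, threshold, protected = character(0),
                           min_channels = 8L) {
  if (!is_chain_model(model))
    stop("prune_channels: channel surgery supports sequential chain models; ",
         "composite detector graphs must keep their coupled layers protected")
  env <- model$env
  widths <- model$widths
  L <- length(widths)
  keeps <- vector("list", L)
  for (i in seq_len(L)) {
    lid <- sprintf("l%d", i - 1L)
    gam <- abs(as.numeric(env$params[[paste0(lid, ".bn_g")]]))
    if (lid %in% protected) { keeps[[i]] <- seq_along(gam); next }
    keep <- which(gam >= threshold)
    if (length(keep) < min_channels)
      keep <- order(gam, decreasing = TRUE)[seq_len(min(min_channels, length(gam)))]
    if (!length(keep))
      stop("prune_channels: layer ", lid, " would lose all channels")
    keeps[[i]] <- sort(keep)
  }
  new_widths <- vapply(keeps, length, integer(1))
  before <- count_parameters(model)
  pruned <- toy_detector(widths = new_widths, img_size = model$cfg$img_size,
                         nc = model$cfg$nc, anchors = model$cfg$anchors,
                         strides_conf = model$strides_conf)
  init_parameters(pruned, seed = 0L)
  penv <- pruned$env
  for (i in seq_len(L)) {
    lid <- sprintf("l%d", i - 1L)
    kin <- if (i == 1L) seq_len(3L) else keeps[[i - 1L]]
    kout <- keeps[[i]]
    penv$params[[paste0(lid, ".w")]] <-
      env$params[[paste0(lid, ".w")]][, , kin, kout, drop = FALSE]
    for (suf in c(".bn_g", ".bn_b"))
      penv$params[[paste0(lid, suf)]] <- env$params[[paste0(lid, suf)]][kout]
    for (suf in c(".bn_m", ".bn_v"))
      penv$buffers[[paste0(lid, suf)]] <- env$buffers[[paste0(lid, suf)]][kout]
  }
  # detection head consumes the last kept channels; its outputs are protected
  penv$params[["head.w"]] <- env$params[["head.w"]][, , keeps[[L]], , drop = FALSE]
  penv$params[["head.b"]] <- env$params[["head.b"]]
  after <- count_parameters(pruned)
  removed <- widths - new_widths
  report <- structure(list(
    keep_masks = keeps,
    layers_touched = sum(removed > 0),
    channels_removed = sum(removed),
    channels_before = sum(widths), channels_kept = sum(new_widths),
    per_layer = data.frame(layer = sprintf("l%d", seq_len(L) - 1L),
                           before = widths, kept = new_widths, removed = removed),
    params_before = before, params_after = after,
    threshold = threshold), class = "prune_report")
  list(model = pruned, report = report)
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("prune_report: %d/%d channels removed over %d layers; params %d -> %d (%.1f%%)\n",
              x$channels_removed, x$channels_before, x$layers_touched,
              x$params_before, x$params_after,
              100 * (1 - x$params_after / x$params_before)))
  invisible(x)
}

#' Fine-tune a pruned model.
#'
#' Continues training from the pruned weights; the graph structure (and
#' hence the parameter count) is left untouched. Zero epochs return the
#' model unchanged.
#' @inheritParams train_detector
#' @return as [train_detector()]
#' @export
finetune <- function(model, train_items, val_items = NULL, epochs = 5L,
                     hyp = default_hyp(), seed = 0L, verbose = FALSE) {
  if (epochs == 0L) return(list(model = model, log = NULL, best_ap = NA_real_))
  train_detector(model, train_items, val_items, epochs = epochs, hyp = hyp,
                 seed = seed, verbose = verbose)
}

#' Run the three-stage compression pipeline.
#'
#' Sparse training (L1 on BN gamma at `cfg$lambda`), global-threshold
#' channel pruning at coefficient `cfg$r`, then fine-tuning with the pruned
#' model as its own pre-trained start. Emits a four-stage summary (initial,
#' sparse, pruned, fine-tuned) of AP, parameter count, weight size and
#' per-image inference time.
#'
#' @param model an initialised chain model (see [toy_detector()])
#' @param train_items,val_items labelled scenes
#' @param cfg a [prune_config()]
#' @param epochs_sparse,epochs_finetune stage epoch budgets
#' @param hyp training hyperparameters
#' @param seed reproducibility seed
#' @return list: final `model`, `report` (prune_report), `summary`
#'   (data.frame with one column per stage), per-stage checkpoints
#' @export
compress_pipeline <- function(model, train_items, val_items, cfg = prune_config(),
                              epochs_sparse = 5L, epochs_finetune = 5L,
                              hyp = default_hyp(), seed = 0L) {
  stage_stats <- function(m) {
    t0 <- proc.time()[["elapsed"]]
    ev <- evaluate_detector(m, val_items)
    dt <- (proc.time()[["elapsed"]] - t0) / length(val_items)
    c(ap = ev$AP, parameters = count_parameters(m),
      size_mb = count_parameters(m) * 4 / 2^20, inference_s = dt)
  }
  s0 <- stage_stats(model)
  tr <- train_detector(model, train_items, val_items, epochs = epochs_sparse,
                       hyp = hyp, seed = seed, sparsity_lambda = cfg$lambda)
  s1 <- stage_stats(tr$model)
  thr <- prune_threshold(tr$model, cfg$r, cfg$protected)
  pr <- prune_channels(tr$model, thr, cfg$protected, cfg$min_channels)
  s2 <- stage_stats(pr$model)
  ft <- finetune(pr$model, train_items, val_items, epochs = epochs_finetune,
                 hyp = hyp, seed = seed + 1L)
  s3 <- stage_stats(ft$model)
  summary <- data.frame(initial = s0, sparse_training = s1,
                        model_pruning = s2, model_finetuning = s3)
  list(model = ft$model, report = pr$report, summary = summary,
       checkpoints = list(sparse = tr$model, pruned = pr$model, final = ft$model))
}

# ---- toy chain detector ----------------------------------------------------

#' Build a small sequential detector for compression experiments.
#'
#' A strided conv-BN-SiLU chain (stride 8 overall) closed by a single-scale
#' anchor head. Every convolution feeds the next layer directly, so channel
#' surgery is exact; this is the test bed for the slimming pipeline.
#'
#' @param widths output channels of the chain layers
#' @param img_size input resolution
#' @param nc class count
#' @param anchors single-scale anchor matrix (rows of `w, h` pixels)
#' @param strides_conf strides per chain layer (2 or 1), recycled
#' @return a chain model (initialise with [init_parameters()])
#' @export
toy_detector <- function(widths = c(16L, 16L, 32L, 32L, 48L, 48L),
                         img_size = 96L, nc = 1L, anchors = NULL,
                         strides_conf = c(2L, 1L, 2L, 1L, 2L, 1L)) {
  if (is.null(anchors))
    anchors <- list(matrix(c(12, 12, 24, 20, 40, 36), 3, 2, byrow = TRUE))
  strides_conf <- rep_len(strides_conf, length(widths))
  env <- new_model_env()
  L <- list()
  cin <- 3L
  for (i in seq_along(widths)) {
    L[[i]] <- list(from = 0,
                   m = mk_conv_bn(env, sprintf("l%d", i - 1L), cin, widths[i], 3L,
                                  strides_conf[i]))
    cin <- widths[i]
  }
  na <- nrow(anchors[[1]]); no <- nc + 5L
  det <- list(kind = "detect", id = "head", nc = nc, na = na, no = no,
              ch = cin, anchors = anchors,
              convs = list(mk_conv_bias(env, "head", cin, na * no, 1L)))
  L[[length(L) + 1L]] <- list(from = length(widths), m = det)
  cfg <- model_config(nc = nc, img_size = img_size, anchors = anchors)
  list(env = env, layers = L, cfg = cfg,
       strides = as.integer(prod(strides_conf)), graph_kind = "chain",
       widths = as.integer(widths), strides_conf = strides_conf,
       variant = "toy")
}
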