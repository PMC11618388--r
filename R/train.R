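# Training: anchor-based target assignment, composite detection loss
# (CIoU box + BCE objectness + BCE class), SGD with momentum and warmup.

#' Default training hyperparameters (scratch-low convention).
#' @return named list
#' @export
default_hyp <- function() {
  list(lr0 = 0.01, lrf = 0.01, momentum = 0.937, weight_decay = 5e-4,
       warmup_epochs = 3, box = 0.05, obj = 1.0, cls = 0.5,
       anchor_t = 4.0, batch_size = 8L)
}

#' Estimate anchors from a labelled set (adaptive anchor calculation).
#'
#' Clusters the label widths/heights at the training resolution with
#' k-means and splits the centroids by area across the detection scales,
#' mirroring the input module's adaptive anchor step.
#'
#' @param items list of `labeled_image`
#' @param img_size training resolution the anchors should live at
#' @param n_scales number of detection scales (3 for the full detector,
#'   1 for the chain test bed)
#' @param per_scale anchors per scale
#' @param seed k-means seed
#' @return list of `per_scale x 2` anchor matrices, sorted by area
#' @export
fit_anchors <- function(items, img_size, n_scales = 3L, per_scale = 3L, seed = 0L) {
  wh <- do.call(rbind, lapply(items, function(it) {
    if (!nrow(it$labels)) return(NULL)
    W <- dim(it$image)[2]; H <- dim(it$image)[1]
    s <- min(img_size / H, img_size / W)
    cbind(it$labels$w * W * s, it$labels$h * H * s)
  }))
  if (is.null(wh) || nrow(wh) < n_scales * per_scale)
    stop("fit_anchors: not enough labels to estimate anchors")
  set.seed(seed)
  km <- stats::kmeans(wh, centers = n_scales * per_scale, nstart = 10L)
  cent <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  lapply(seq_len(n_scales), function(k)
    unname(cent[((k - 1L) * per_scale + 1L):(k * per_scale), , drop = FALSE]))
}

# Assign ground-truth boxes to anchors/cells for one scale.
# targets: data.frame(n, cx, cy, w, h) in letterboxed pixel units.
build_targets_scale <- function(targets, anchors, stride, Hh, Ww, anchor_t = 4) {
  if (!nrow(targets)) return(NULL)
  out <- NULL
  g <- 0.5
  for (a in seq_len(nrow(anchors))) {
    aw <- anchors[a, 1] / stride; ah <- anchors[a, 2] / stride
    tw <- targets$w / stride; th <- targets$h / stride
    r <- pmax(tw / aw, aw / tw, th / ah, ah / th)
    sel <- which(r < anchor_t)
    if (!length(sel)) next
    tx <- targets$cx[sel] / stride; ty <- targets$cy[sel] / stride
    base <- data.frame(n = targets$n[sel], a = a, x = tx, y = ty,
                       w = tw[sel], h = th[sel])
    # centre cell plus the two nearest neighbour cells
    cand <- list(base)
    fx <- base$x %% 1; fy <- base$y %% 1
    l <- fx < g & base$x > 1; r2 <- fx > (1 - g) & base$x < Ww - 1
    u <- fy < g & base$y > 1; d2 <- fy > (1 - g) & base$y < Hh - 1
    if (any(l)) cand <- c(cand, list(transform(base[l, ], x = x - 1)))
    if (any(r2)) cand <- c(cand, list(transform(base[r2, ], x = x + 1)))
    if (any(u)) cand <- c(cand, list(transform(base[u, ], y = y - 1)))
    if (any(d2)) cand <- c(cand, list(transform(base[d2, ], y = y + 1)))
    cc <- do.call(rbind, cand)
    gx <- floor(cc$x); gy <- floor(cc$y)
    ok <- gx >= 0 & gx < Ww & gy >= 0 & gy < Hh
    cc <- cc[ok, ]; gx <- gx[ok]; gy <- gy[ok]
    out <- rbind(out, data.frame(n = cc$n, a = a, gx = gx, gy = gy,
                                 tx = cc$x - gx, ty = cc$y - gy,
                                 tw = cc$w, th = cc$h))
  }
  # candidate cells may repeat when offsets collide: keep first occurrence
  if (!is.null(out)) out[!duplicated(out[, c("n", "a", "gx", "gy")]), ] else NULL
}

ciou_vec <- function(px, py, pw, ph, tx, ty, tw, th) {
  # complete IoU between predicted and target xywh boxes (vectors on tape)
  eps <- 1e-7
  pX1 <- ag_sub(px, ag_mul(pw, 0.5)); pX2 <- ag_add(px, ag_mul(pw, 0.5))
  pY1 <- ag_sub(py, ag_mul(ph, 0.5)); pY2 <- ag_add(py, ag_mul(ph, 0.5))
  tX1 <- tx - tw / 2; tX2 <- tx + tw / 2; tY1 <- ty - th / 2; tY2 <- ty + th / 2
  iw <- ag_pmax(ag_sub(ag_pmin(pX2, tX2), ag_pmax(pX1, tX1)), 0)
  ih <- ag_pmax(ag_sub(ag_pmin(pY2, tY2), ag_pmax(pY1, tY1)), 0)
  inter <- ag_mul(iw, ih)
  union <- ag_add(ag_sub(ag_add(ag_mul(pw, ph), tw * th), inter), eps)
  i_ou <- ag_div(inter, union)
  cw <- ag_add(ag_sub(ag_pmax(pX2, tX2), ag_pmin(pX1, tX1)), eps)
  ch <- ag_add(ag_sub(ag_pmax(pY2, tY2), ag_pmin(pY1, tY1)), eps)
  c2 <- ag_add(ag_add(ag_sq(cw), ag_sq(ch)), eps)
  rho2 <- ag_add(ag_sq(ag_sub(px, tx)), ag_sq(ag_sub(py, ty)))
  v <- ag_mul(ag_sq(ag_sub(ag_atan(ag_div(pw, ag_add(ph, eps))), atan(tw / (th + eps)))),
              4 / pi^2)
  alpha <- vof(v) / (1 - vof(i_ou) + vof(v) + eps)   # detached mixing weight
  ag_sub(i_ou, ag_add(ag_div(rho2, c2), ag_mul(v, alpha)))
}

# composite loss over the three scale maps for one batch
detector_loss <- function(model, preds, targets_px, hyp) {
  nc <- model$cfg$nc; na <- nrow(model$cfg$anchors[[1]]); no <- nc + 5L
  balance <- c(4.0, 1.0, 0.4)
  lbox <- 0; lobj <- 0; lcls <- 0; total_pos <- 0L
  B <- dim(vof(preds[[1]]))[4]
  for (k in seq_along(preds)) {
    p <- preds[[k]]
    d <- dim(vof(p)); Hh <- d[1]; Ww <- d[2]
    stride <- model$strides[k]
    tt <- build_targets_scale(targets_px, model$cfg$anchors[[k]], stride, Hh, Ww,
                              hyp$anchor_t)
    tobj <- array(0, dim = c(Hh, Ww, na, B))
    if (!is.null(tt) && nrow(tt)) {
      total_pos <- total_pos + nrow(tt)
      flat_idx <- function(ch) tt$gy + 1 + Hh * tt$gx + Hh * Ww * (ch - 1) +
        Hh * Ww * d[3] * (tt$n - 1)
      b0 <- (tt$a - 1L) * no
      px <- ag_sub(ag_mul(ag_sigmoid(ag_gather(p, flat_idx(b0 + 1L))), 2), 0.5)
      py <- ag_sub(ag_mul(ag_sigmoid(ag_gather(p, flat_idx(b0 + 2L))), 2), 0.5)
      aw <- model$cfg$anchors[[k]][tt$a, 1] / stride
      ah <- model$cfg$anchors[[k]][tt$a, 2] / stride
      pw <- ag_mul(ag_sq(ag_mul(ag_sigmoid(ag_gather(p, flat_idx(b0 + 3L))), 2)), aw)
      ph <- ag_mul(ag_sq(ag_mul(ag_sigmoid(ag_gather(p, flat_idx(b0 + 4L))), 2)), ah)
      ci <- ciou_vec(px, py, pw, ph, tt$tx, tt$ty, tt$tw, tt$th)
      lbox <- ag_add(lbox, ag_mean(ag_sub(1, ci)))
      # objectness target = detached positive IoU
      civ <- pmax(0, vof(ci))
      tobj[cbind(tt$gy + 1L, tt$gx + 1L, tt$a, tt$n)] <- civ
      if (nc > 1L) stop("detector_loss: multi-class training not implemented")
      # single class: push the class channel to 1 at positive cells so the
      # decoded confidence obj * cls reduces to the objectness
      pc <- ag_gather(p, flat_idx(b0 + 6L))
      lcls <- ag_add(lcls, ag_mean(ag_bce_logits(pc, rep(1, nrow(tt)))))
    }
    obj_ch <- as.integer(outer(5L, (seq_len(na) - 1L) * no, `+`))
    pobj <- ag_slice(p, 3L, obj_ch)
    bal <- if (length(preds) == 3L) balance[k] else 1.0
    lobj <- ag_add(lobj, ag_mul(ag_mean(ag_bce_logits(pobj, tobj)), bal))
  }
  loss <- ag_mul(ag_add(ag_add(ag_mul(lbox, hyp$box), ag_mul(lobj, hyp$obj)),
                        ag_mul(lcls, hyp$cls)), B)
  list(loss = loss, lbox = vof(lbox), lobj = vof(lobj), n_pos = total_pos)
}

sgd_step <- function(env, state, lr, momentum, weight_decay) {
  for (pid in ls(env$grads)) {
    g <- env$grads[[pid]]
    if (is.null(g)) next
    if (weight_decay > 0 && grepl("\\.w$", pid))
      g <- g + weight_decay * env$params[[pid]]
    v <- state[[pid]]
    v <- if (is.null(v)) g else momentum * v + g
    state[[pid]] <- v
    env$params[[pid]] <- env$params[[pid]] - lr * v
  }
  invisible(NULL)
}

zero_grads <- function(env) {
  rm(list = ls(env$grads), envir = env$grads)
}

# letterboxed batch: images to (S, S, 3, B) plus pixel-space targets
make_batch <- function(items, size) {
  B <- length(items)
  x <- array(0, dim = c(size, size, 3L, B))
  targets <- NULL
  for (i in seq_len(B)) {
    it <- items[[i]]
    lb <- letterbox(it$image, size)
    x[, , , i] <- lb$image
    if (nrow(it$labels)) {
      W <- dim(it$image)[2]; H <- dim(it$image)[1]
      targets <- rbind(targets, data.frame(
        n = i,
        cx = it$labels$cx * W * lb$scale + lb$pad_x,
        cy = it$labels$cy * H * lb$scale + lb$pad_y,
        w = it$labels$w * W * lb$scale,
        h = it$labels$h * H * lb$scale))
    }
  }
  list(x = x, targets = targets %||% data.frame(n = integer(0), cx = numeric(0),
                                               cy = numeric(0), w = numeric(0),
                                               h = numeric(0)))
}

#' Train a detector with SGD.
#'
#' Standard composite loss (CIoU box + objectness BCE, single class),
#' momentum SGD with linear warmup and linear decay to `lr0 * lrf`,
#' optional L1 subgradient sparsity on prunable BN scales (the first stage
#' of the slimming pipeline), per-epoch validation AP logging and retention
#' of the best-AP weights.
#'
#' @param model an initialised detector
#' @param train_items,val_items lists of `labeled_image`
#' @param epochs training epochs
#' @param hyp hyperparameters, see [default_hyp()]
#' @param seed shuffling/reproducibility seed
#' @param sparsity_lambda L1 penalty on prunable BN gamma (0 = off)
#' @param eval_every validate every this many epochs
#' @param target_ap optional early-stop AP threshold
#' @param max_seconds wall-clock training budget; the epoch loop stops when
#'   it is exhausted (the best weights so far are kept)
#' @param verbose print a line per epoch
#' @return list: the trained `model`, `log` (data.frame of epoch, loss, AP),
#'   `best_ap`
#' @export
train_detector <- function(model, train_items, val_items = NULL, epochs = 10L,
                           hyp = default_hyp(), seed = 0L, sparsity_lambda = 0,
                           eval_every = 1L, target_ap = NULL, verbose = FALSE,
                           max_seconds = Inf) {
  t_start <- proc.time()[["elapsed"]]
  if (!length(train_items)) stop("train_detector: empty training set")
  for (it in train_items)
    if (nrow(it$labels) && any(it$labels$w <= 0 | it$labels$h <= 0))
      stop("train_detector: degenerate labels (non-positive extent)")
  env <- model$env
  size <- model$cfg$img_size
  state <- new.env(parent = emptyenv())
  bs <- min(hyp$batch_size, length(train_items))
  nb <- ceiling(length(train_items) / bs)
  warmup_iters <- max(1, round(hyp$warmup_epochs * nb))
  log <- NULL; best_ap <- -Inf; best <- NULL; iter <- 0L
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(train_items))
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      iter <- iter + 1L
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, length(ord))]
      batch <- make_batch(train_items[idx], size)
      preds <- forward_detector(model, batch$x, train = TRUE)
      zero_grads(env)
      lr_frac <- if (iter <= warmup_iters) iter / warmup_iters else 1
      decay <- 1 - (1 - hyp$lrf) * (ep - 1) / max(1, epochs - 1)
      lr <- hyp$lr0 * lr_frac * decay
      ls <- detector_loss(model, preds, batch$targets, hyp)
      ag_backward(ls$loss, env$grads)
      if (sparsity_lambda > 0) sparse_step(model, sparsity_lambda)
      sgd_step(env, state, lr, hyp$momentum, hyp$weight_decay)
      ep_loss <- ep_loss + vof(ls$loss) / length(idx)
    }
    ap <- NA_real_
    if (!is.null(val_items) && (ep %% eval_every == 0L || ep == epochs)) {
      refresh_bn_stats(model, train_items, batch_size = bs)
      ev <- try(evaluate_detector(model, val_items), silent = TRUE)
      if (!inherits(ev, "try-error")) {
        ap <- ev$AP
        if (ap > best_ap) {
          best_ap <- ap
          best <- as.list(env$params)
        }
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb, ap = ap))
    if (verbose) message(sprintf("epoch %d loss %.4f AP %.3f", ep, ep_loss / nb, ap))
    if (!is.null(target_ap) && !is.na(ap) && ap >= target_ap) break
    if (proc.time()[["elapsed"]] - t_start > max_seconds) break
  }
  if (!is.null(best)) for (nm in names(best)) env$params[[nm]] <- best[[nm]]
  list(model = model, log = log, best_ap = if (is.finite(best_ap)) best_ap else NA_real_)
}
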