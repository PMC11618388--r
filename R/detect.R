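# Inference utilities: letterboxing, prediction decoding, NMS wrapper.

resize_nearest <- function(img, H2, W2) {
  H <- dim(img)[1]; W <- dim(img)[2]
  yi <- pmin(H, pmax(1L, round((seq_len(H2) - 0.5) * H / H2 + 0.5)))
  xi <- pmin(W, pmax(1L, round((seq_len(W2) - 0.5) * W / W2 + 0.5)))
  img[yi, xi, , drop = FALSE]
}

#' Letterbox an image to a square side with aspect-preserving resize.
#'
#' @param img array `H x W x 3`
#' @param size target side (multiple of 32)
#' @param fill padding intensity (gray convention)
#' @return list with `image` (size x size x 3), `scale`, `pad_x`, `pad_y`
#' @export
letterbox <- function(img, size, fill = 114 / 255) {
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- min(size / H, size / W)
  H2 <- round(H * s); W2 <- round(W * s)
  rs <- resize_nearest(img, H2, W2)
  out <- array(fill, dim = c(size, size, 3))
  py <- (size - H2) %/% 2L; px <- (size - W2) %/% 2L
  out[py + seq_len(H2), px + seq_len(W2), ] <- rs
  list(image = out, scale = s, pad_x = px, pad_y = py)
}

# image array (H, W, 3) -> model input (H, W, 3, 1)
to_input <- function(img) array(img, dim = c(dim(img)[1], dim(img)[2], 3L, 1L))

# decode one scale's raw map for one image into xyxy boxes + confidence
decode_scale <- function(pmap, anchors, stride, nc) {
  d <- dim(pmap); Hh <- d[1]; Ww <- d[2]
  na <- nrow(anchors); no <- nc + 5L
  sig <- 1 / (1 + exp(-pmap))
  boxes <- NULL; confs <- NULL; cls <- NULL
  gx <- matrix(rep(seq_len(Ww) - 1L, each = Hh), Hh, Ww)
  gy <- matrix(rep(seq_len(Hh) - 1L, Ww), Hh, Ww)
  for (a in seq_len(na)) {
    b0 <- (a - 1L) * no
    px <- (2 * sig[, , b0 + 1L, 1] - 0.5 + gx) * stride
    py <- (2 * sig[, , b0 + 2L, 1] - 0.5 + gy) * stride
    pw <- (2 * sig[, , b0 + 3L, 1])^2 * anchors[a, 1]
    ph <- (2 * sig[, , b0 + 4L, 1])^2 * anchors[a, 2]
    obj <- sig[, , b0 + 5L, 1]
    cbest <- if (nc == 1L) sig[, , b0 + 6L, 1] else
      apply(sig[, , b0 + 5L + seq_len(nc), 1, drop = FALSE], c(1, 2), max)
    conf <- obj * cbest
    boxes <- rbind(boxes, cbind(as.numeric(px - pw / 2), as.numeric(py - ph / 2),
                                as.numeric(px + pw / 2), as.numeric(py + ph / 2)))
    confs <- c(confs, as.numeric(conf))
  }
  list(boxes = boxes, conf = confs)
}

#' Run inference on images and return detections in original pixel frames.
#'
#' Letterboxes each image to the model resolution, decodes the three scale
#' maps, filters by confidence, applies class-agnostic greedy NMS and maps
#' box coordinates back to the input image frame.
#'
#' @param model an initialised detector
#' @param images list of `H x W x 3` arrays (or `labeled_image`s)
#' @param conf_thr confidence threshold
#' @param iou_thr NMS IoU threshold
#' @param max_det maximum detections per image
#' @return list per image: `boxes` (matrix `x_min, y_min, x_max, y_max`),
#'   `conf` (sorted descending)
#' @export
predict_detector <- function(model, images, conf_thr = 0.25, iou_thr = 0.45,
                             max_det = 300L) {
  size <- model$cfg$img_size
  anchors <- model$cfg$anchors
  lapply(images, function(im) {
    img <- if (inherits(im, "labeled_image")) im$image else im
    lb <- letterbox(img, size)
    preds <- forward_detector(model, to_input(lb$image), train = FALSE)
    boxes <- NULL; confs <- NULL
    for (k in seq_along(preds)) {
      dec <- decode_scale(vof(preds[[k]]), anchors[[k]], model$strides[k], model$cfg$nc)
      keep <- dec$conf >= conf_thr
      boxes <- rbind(boxes, dec$boxes[keep, , drop = FALSE])
      confs <- c(confs, dec$conf[keep])
    }
    if (is.null(boxes) || !nrow(boxes))
      return(list(boxes = matrix(0, 0, 4), conf = numeric(0)))
    if (nrow(boxes) > 1000L) {          # pre-NMS candidate cap
      top <- order(confs, decreasing = TRUE)[1:1000]
      boxes <- boxes[top, , drop = FALSE]; confs <- confs[top]
    }
    keep <- nms(boxes, confs, iou_thr)
    keep <- keep[seq_len(min(length(keep), max_det))]
    boxes <- boxes[keep, , drop = FALSE]; confs <- confs[keep]
    # map back to the original frame
    boxes[, c(1, 3)] <- (boxes[, c(1, 3)] - lb$pad_x) / lb$scale
    boxes[, c(2, 4)] <- (boxes[, c(2, 4)] - lb$pad_y) / lb$scale
    W <- dim(img)[2]; H <- dim(img)[1]
    boxes[, 1] <- pmax(0, pmin(boxes[, 1], W)); boxes[, 3] <- pmax(0, pmin(boxes[, 3], W))
    boxes[, 2] <- pmax(0, pmin(boxes[, 2], H)); boxes[, 4] <- pmax(0, pmin(boxes[, 4], H))
    list(boxes = boxes, conf = confs)
  })
}

#' Evaluate a detector on labelled scenes at IoU 0.5.
#'
#' @param model an initialised detector
#' @param items list of `labeled_image`
#' @param conf_thr confidence for headline P/R (`NULL`: best-F1 point)
#' @param nms_conf low decode threshold used before the PR sweep
#' @return an `eval_result`
#' @export
evaluate_detector <- function(model, items, conf_thr = NULL, nms_conf = 0.005) {
  preds <- predict_detector(model, items, conf_thr = nms_conf)
  truths <- lapply(items, function(it) {
    H <- dim(it$image)[1]; W <- dim(it$image)[2]
    if (!nrow(it$labels)) return(matrix(0, 0, 4))
    labels_to_px(it$labels, W, H)
  })
  evaluate_detections(preds, truths, conf_thr = conf_thr)
}
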