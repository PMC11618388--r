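# Detection metrics: IoU, greedy confidence-ordered matching, average
# precision as the area under the monotone precision envelope, and
# dataset-level evaluation at IoU 0.5.

#' Intersection over union of two axis-aligned boxes.
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)` in pixel coordinates.
#' Degenerate (zero-area) boxes overlap nothing by definition.
#' @param a,b numeric length-4 boxes
#' @return IoU in `[0, 1]`
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) return(0)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

iou_matrix <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(matrix(0, nrow(A), nrow(B)))
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- iou(A[i, ], B[j, ])
  out
}

#' Greedy one-to-one matching of detections against ground truth.
#'
#' Detections are taken in descending confidence order; each claims the
#' highest-IoU unmatched ground-truth box with IoU above the threshold.
#' Unclaimed ground truths are false negatives.
#'
#' @param boxes detection matrix, columns `x_min, y_min, x_max, y_max`
#' @param conf detection confidences
#' @param gt ground-truth box matrix in the same format
#' @param iou_thr IoU threshold (default 0.5)
#' @return list with logical `tp` per detection (in the original order),
#'   counts `TP`, `FP`, `FN`, and the processing `order`
#' @export
match_detections <- function(boxes, conf, gt, iou_thr = 0.5) {
  boxes <- as.matrix(boxes); gt <- as.matrix(gt)
  nd <- nrow(boxes); ng <- nrow(gt)
  tp <- logical(nd)
  if (nd > 0) {
    ord <- order(conf, decreasing = TRUE)
    taken <- logical(ng)
    if (ng > 0) {
      M <- iou_matrix(boxes, gt)
      for (i in ord) {
        cand <- which(!taken & M[i, ] > iou_thr)
        if (length(cand)) {
          j <- cand[which.max(M[i, cand])]
          taken[j] <- TRUE
          tp[i] <- TRUE
        }
      }
    }
  } else ord <- integer(0)
  list(tp = tp, TP = sum(tp), FP = nd - sum(tp),
       FN = if (ng > 0) ng - sum(tp) else 0L, order = ord)
}

#' Average precision from ranked detection labels.
#'
#' Builds the cumulative precision-recall curve over descending confidence
#' and integrates the monotone-decreasing precision envelope over recall
#' (the continuous scheme: each recall increment contributes its envelope
#' precision).
#'
#' @param tp logical TP/FP label per detection
#' @param conf detection confidences
#' @param n_gt number of ground-truth objects (must be >= 1)
#' @return list with `ap` and the PR curve (`recall`, `precision`)
#' @export
average_precision <- function(tp, conf, n_gt) {
  if (n_gt < 1) stop("average_precision: undefined for n_gt = 0")
  if (!length(tp)) return(list(ap = 0, recall = numeric(0), precision = numeric(0)))
  ord <- order(conf, decreasing = TRUE)
  tp <- as.logical(tp[ord])
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  mrec <- c(0, rec, 1)
  mpre <- c(1, prec, 0)
  env <- rev(cummax(rev(mpre)))
  idx <- which(diff(mrec) > 0)
  ap <- sum((mrec[idx + 1] - mrec[idx]) * env[idx + 1])
  list(ap = ap, recall = rec, precision = prec)
}

#' Evaluate detections over a labelled dataset at IoU 0.5.
#'
#' @param predictions list per image: each a list with `boxes` (matrix) and
#'   `conf` (vector); may be empty
#' @param truths list per image of ground-truth box matrices
#' @param conf_thr confidence threshold for the headline P/R figures; if
#'   `NULL`, the threshold maximising F1 on the PR curve is used
#' @param iou_thr IoU threshold (default 0.5)
#' @return list of class `eval_result`: `TP`, `FP`, `FN`, `P`, `R`, `AP`,
#'   `pr_points` (data.frame), `n_gt`
#' @export
evaluate_detections <- function(predictions, truths, conf_thr = NULL, iou_thr = 0.5) {
  if (length(predictions) != length(truths))
    stop("evaluate_detections: prediction/truth image counts differ")
  all_tp <- logical(0); all_conf <- numeric(0); n_gt <- 0L
  for (i in seq_along(truths)) {
    gt <- truths[[i]]
    p <- predictions[[i]]
    nb <- if (is.null(p$boxes)) 0L else nrow(as.matrix(p$boxes))
    n_gt <- n_gt + if (is.null(gt)) 0L else nrow(as.matrix(gt))
    if (nb > 0) {
      m <- match_detections(p$boxes, p$conf, if (is.null(gt)) matrix(0, 0, 4) else gt, iou_thr)
      all_tp <- c(all_tp, m$tp); all_conf <- c(all_conf, p$conf)
    }
  }
  if (n_gt == 0L) stop("evaluate_detections: dataset has no ground-truth objects")
  apr <- average_precision(all_tp, all_conf, n_gt)
  ord <- order(all_conf, decreasing = TRUE)
  stp <- all_tp[ord]; sconf <- all_conf[ord]
  ctp <- cumsum(stp); cfp <- cumsum(!stp)
  precs <- ctp / pmax(ctp + cfp, 1); recs <- ctp / n_gt
  if (is.null(conf_thr)) {
    f1 <- 2 * precs * recs / pmax(precs + recs, 1e-12)
    k <- if (length(f1)) which.max(f1) else 0L
    conf_thr <- if (k > 0) sconf[k] else 0.5
  }
  keep <- sum(sconf >= conf_thr)
  TP <- if (keep > 0) ctp[keep] else 0L
  FP <- if (keep > 0) cfp[keep] else 0L
  FN <- n_gt - TP
  structure(list(TP = TP, FP = FP, FN = FN,
                 P = if (TP + FP > 0) TP / (TP + FP) else 0,
                 R = TP / n_gt, AP = apr$ap, conf_thr = conf_thr, n_gt = n_gt,
                 pr_points = data.frame(recall = apr$recall, precision = apr$precision)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: P=%.3f R=%.3f AP@0.5=%.3f (TP=%d FP=%d FN=%d, n_gt=%d, conf>=%.3f)\n",
              x$P, x$R, x$AP, x$TP, x$FP, x$FN, x$n_gt, x$conf_thr))
  invisible(x)
}

#' Greedy non-maximum suppression.
#'
#' Stable tie-break: confidence descending, then box area descending, so the
#' result is independent of input ordering among equal-confidence boxes.
#' @param boxes matrix `x_min, y_min, x_max, y_max`
#' @param conf confidences
#' @param iou_thr suppression threshold
#' @return integer indices of the surviving boxes
#' @export
nms <- function(boxes, conf, iou_thr = 0.45) {
  boxes <- as.matrix(boxes)
  if (!nrow(boxes)) return(integer(0))
  area <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  ord <- order(-conf, -area)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    ious <- vapply(rest, function(j) iou(boxes[i, ], boxes[j, ]), numeric(1))
    ord <- rest[ious <= iou_thr]
  }
  keep
}
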