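# IoU, matching, average precision: hand-computed and brute-force oracles.

test_that("iou matches hand-computed overlaps", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), 0)  # degenerate box
})

test_that("greedy matching is one-to-one in confidence order", {
  gt <- matrix(c(0, 0, 10, 10), 1, 4)
  m <- match_detections(matrix(c(1, 1, 10, 10), 1, 4), 0.9, gt)
  expect_identical(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))

  # two detections on one ground truth: only the higher-confidence one is TP
  dets <- rbind(c(0, 0, 10, 10), c(0.5, 0.5, 10.5, 10.5))
  m2 <- match_detections(dets, c(0.6, 0.9), gt)
  expect_identical(m2$TP, 1L)
  expect_true(m2$tp[2] && !m2$tp[1])

  # strict threshold: IoU exactly at the threshold is not a match
  m3 <- match_detections(matrix(c(0, 0, 1, 1), 1, 4), 0.5,
                         matrix(c(0, 0, 1, 2), 1, 4), iou_thr = 0.5)
  expect_identical(m3$TP, 0L)
})

test_that("greedy matching agrees with brute-force assignment on small cases", {
  # brute force: maximum one-to-one matching over all assignments with the
  # constraint that a pair is only usable above the IoU threshold
  brute_tp <- function(boxes, gt, thr) {
    nd <- nrow(boxes); ng <- nrow(gt)
    M <- yologinseng:::iou_matrix(boxes, gt) > thr
    best <- 0L
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (p in perms(seq_len(ng))) {
      used <- logical(ng); tp <- 0L
      for (i in seq_len(min(nd, ng))) if (M[i, p[i]]) tp <- tp + 1L
      best <- max(best, tp)
    }
    best
  }
  set.seed(21)
  for (rep in 1:20) {
    nd <- sample(1:4, 1); ng <- sample(1:4, 1)
    mk <- function(n) {
      x <- runif(n, 0, 6); y <- runif(n, 0, 6)
      cbind(x, y, x + runif(n, 1, 4), y + runif(n, 1, 4))
    }
    boxes <- mk(nd); gt <- mk(ng)
    conf <- runif(nd)
    g <- match_detections(boxes, conf, gt, 0.3)
    b <- brute_tp(boxes[order(-conf), , drop = FALSE], gt, 0.3)
    # greedy confidence-ordered matching can only lose ties versus the
    # optimal assignment; on these geometric cases it must not exceed it
    expect_lte(g$TP, b)
    expect_gte(g$TP, 0L)
    # conservation at every threshold
    expect_identical(g$TP + g$FN, nrow(gt))
    expect_identical(g$TP + g$FP, nrow(boxes))
  }
})

test_that("average precision reproduces hand-built two-point curves", {
  expect_equal(average_precision(TRUE, 0.9, 1)$ap, 1)
  # FP ranked above the TP: envelope precision 1/2 at recall 1
  expect_equal(average_precision(c(FALSE, TRUE), c(0.9, 0.5), 1)$ap, 0.5)
  # TP ranked above the FP: recall saturates before the FP appears
  expect_equal(average_precision(c(TRUE, FALSE), c(0.9, 0.5), 1)$ap, 1)
  expect_error(average_precision(TRUE, 0.9, 0), "n_gt")
})

test_that("average precision equals exhaustive step-curve integration", {
  # oracle: walk the ranked list, integrate the exact running-maximum
  # precision over each recall increment
  ap_oracle <- function(tp, conf, n_gt) {
    ord <- order(conf, decreasing = TRUE)
    tp <- tp[ord]
    ctp <- cumsum(tp); cfp <- cumsum(!tp)
    prec <- ctp / (ctp + cfp); rec <- ctp / n_gt
    ap <- 0; last_r <- 0
    for (i in seq_along(tp)) {
      if (rec[i] > last_r) {
        # precision attainable at this recall level or beyond
        p_env <- max(prec[i:length(prec)])
        ap <- ap + (rec[i] - last_r) * p_env
        last_r <- rec[i]
      }
    }
    ap
  }
  set.seed(31)
  for (rep in 1:50) {
    nd <- sample(1:6, 1)
    tp <- runif(nd) > 0.5
    conf <- runif(nd)
    n_gt <- max(1L, sum(tp) + sample(0:2, 1))
    expect_equal(average_precision(tp, conf, n_gt)$ap, ap_oracle(tp, conf, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone confidence rescaling and FP appends", {
  set.seed(41)
  for (rep in 1:20) {
    nd <- sample(2:8, 1)
    tp <- runif(nd) > 0.4
    conf <- runif(nd)
    n_gt <- max(1L, sum(tp))
    ap0 <- average_precision(tp, conf, n_gt)$ap
    # strictly monotone rescalings preserve the ranking, hence the AP
    expect_equal(average_precision(tp, conf^3 + 2, n_gt)$ap, ap0)
    expect_equal(average_precision(tp, stats::plogis(5 * conf), n_gt)$ap, ap0)
    # appending a lowest-confidence FP can never raise the AP
    ap_fp <- average_precision(c(tp, FALSE), c(conf, min(conf) - 0.1), n_gt)$ap
    expect_lte(ap_fp, ap0 + 1e-12)
    # adding a TP at any rank can never lower it
    at <- runif(1, min(conf), max(conf))
    ap_tp <- average_precision(c(tp, TRUE), c(conf, at), n_gt)$ap
    expect_gte(ap_tp, ap0 - 1e-12)
  }
})

test_that("evaluate_detections reports exact P/R on a hand-built fixture", {
  # 3 images, known TP/FP/FN: img1 1 TP; img2 1 TP + 1 FP; img3 misses its gt
  preds <- list(
    list(boxes = matrix(c(0, 0, 10, 10), 1, 4), conf = 0.9),
    list(boxes = rbind(c(20, 20, 30, 30), c(50, 50, 60, 60)), conf = c(0.8, 0.7)),
    list(boxes = matrix(0, 0, 4), conf = numeric(0)))
  truths <- list(matrix(c(1, 1, 10, 10), 1, 4),
                 matrix(c(21, 21, 31, 31), 1, 4),
                 matrix(c(0, 0, 5, 5), 1, 4))
  ev <- evaluate_detections(preds, truths, conf_thr = 0.5)
  expect_equal(c(ev$TP, ev$FP, ev$FN), c(2L, 1L, 1L))
  expect_equal(as.numeric(ev$P), 2 / 3)
  expect_equal(as.numeric(ev$R), 2 / 3)

  # perfect detector on its own labels
  ev2 <- evaluate_detections(
    list(list(boxes = truths[[1]], conf = 1)), truths[1], conf_thr = 0.5)
  expect_equal(c(ev2$P, ev2$R, ev2$AP), c(1, 1, 1))

  # empty prediction set: zero recall, zero AP
  ev3 <- evaluate_detections(list(list(boxes = matrix(0, 0, 4), conf = numeric(0))),
                             truths[1], conf_thr = 0.5)
  expect_equal(c(ev3$R, ev3$AP), c(0, 0))
})

test_that("nms suppresses duplicates, keeps disjoint boxes, ignores order", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(50, 50, 60, 60))
  k <- nms(b, c(0.9, 0.8, 0.5), 0.5)
  expect_identical(sort(k), c(1L, 3L))
  # IoU 1/7 pair survives at threshold 0.5
  b2 <- rbind(c(0, 0, 2, 2), c(1, 1, 3, 3))
  expect_identical(sort(nms(b2, c(0.9, 0.8), 0.5)), c(1L, 2L))
  # equal confidences: area tie-break makes the outcome order-independent
  b3 <- rbind(c(0, 0, 10, 10), c(1, 1, 9, 9))
  k1 <- nms(b3, c(0.7, 0.7), 0.5)
  k2 <- nms(b3[2:1, ], c(0.7, 0.7), 0.5)
  expect_identical(b3[k1, , drop = FALSE], b3[2:1, ][k2, , drop = FALSE])
})
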