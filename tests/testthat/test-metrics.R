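# Detection metrics against closed forms and brute-force oracles.

test_that("iou on hand-computable boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 2 / 6)
  expect_warning(v <- iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
  expect_equal(v, 0)
})

test_that("nms keeps the top box among duplicates and single boxes", {
  expect_equal(nms(matrix(c(0, 0, 2, 2), 1), 0.9), 1L)
  b <- rbind(c(0, 0, 2, 2), c(0, 0, 2, 2))
  expect_equal(nms(b, c(0.9, 0.8), 0.7), 1L)
})

test_that("precision/recall/F1 formulas and conventions", {
  expect_equal(precision_recall_f1(72, 28, 0)[["precision"]], 0.72)
  z <- precision_recall_f1(0, 0, 0)
  expect_equal(unname(z), c(0, 0, 0))
  # F1 from the harmonic-mean formula at the printed operating point
  p <- 0.720; r <- 0.662
  expect_equal(round(2 * p * r / (p + r), 3), 0.690)
})

test_that("average precision on tiny hand-built curves", {
  expect_equal(average_precision(TRUE, 1), 1.0)
  expect_equal(average_precision(c(FALSE, TRUE), 1), 0.5)
  expect_true(is.na(average_precision(logical(0), 0)))
  expect_equal(average_precision(logical(0), 2), 0)
})

test_that("mean AP is the arithmetic mean over defined classes", {
  expect_equal(mean_ap(1.0), 1.0)
  expect_equal(mean_ap(c(1.0, 0.0)), 0.5)
  set.seed(1)
  aps <- runif(5)
  expect_equal(mean_ap(aps), mean(aps))
  expect_equal(mean_ap(c(0.3, NA, 0.5)), 0.4)
  expect_equal(mean_ap(rep(0.37, 4)), 0.37)
})

test_that("AP is invariant to positive confidence rescaling and monotone in added hits", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    tp <- runif(n) < 0.5
    ngt <- sum(tp) + sample(0:3, 1)
    sc <- sort(runif(n), decreasing = TRUE)
    ap1 <- average_precision(tp, ngt)
    # rescaling confidences preserves order hence AP
    expect_equal(average_precision(tp[order(sc * 7.3, decreasing = TRUE)], ngt), ap1)
    # an extra correct detection above all thresholds never decreases AP
    ap2 <- average_precision(c(TRUE, tp), ngt + 1)
    expect_gte(ap2 + 1e-12, ap1)
  }
})

test_that("nms, AP and confusion matrix match brute-force oracles on random instances", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(1:20, 1)
    boxes <- random_boxes(n)
    scores <- runif(n)
    cls <- sample(0:2, n, replace = TRUE)
    thr <- runif(1, 0.2, 0.8)
    expect_equal(nms(boxes, scores, thr), oracle_nms(boxes, scores, thr))
    expect_equal(nms(boxes, scores, thr, classes = cls),
                 oracle_nms(boxes, scores, thr, classes = cls))
    tp <- runif(n) < 0.5
    ngt <- sum(tp) + sample(0:4, 1)
    ord <- order(scores, decreasing = TRUE)
    expect_equal(average_precision(tp[ord], ngt), oracle_ap(tp[ord], ngt),
                 tolerance = 1e-12)
  }
})

test_that("confusion matrix handles perfect, empty and mixed predictions", {
  gt <- data.frame(image = c(1, 1, 2), class = c(0, 1, 2),
                   x1 = c(0, 50, 10), y1 = c(0, 50, 10),
                   x2 = c(20, 80, 40), y2 = c(20, 80, 40))
  det_perfect <- cbind(gt, score = 1)
  cm <- confusion_matrix(det_perfect, gt, 3)
  expect_equal(diag(cm)[1:3], c(class0 = 1, class1 = 1, class2 = 1))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # no detections: all ground truths fall into the background column
  cm0 <- confusion_matrix(det_perfect[0, ], gt, 3)
  expect_equal(unname(cm0[1:3, 4]), c(1, 1, 1))
  # a wrong-class detection lands off-diagonal
  det_wrong <- det_perfect
  det_wrong$class[1] <- 1
  cm2 <- confusion_matrix(det_wrong, gt, 3)
  expect_equal(unname(cm2[1, 2]), 1)
})

test_that("pooled evaluation returns the headline fields and a perfect oracle scores 1", {
  gt <- data.frame(image = rep(1:4, each = 2), class = rep(0:1, 4),
                   x1 = runif(8, 0, 40), y1 = runif(8, 0, 40))
  gt$x2 <- gt$x1 + 30
  gt$y2 <- gt$y1 + 25
  det <- oracle_detector(gt)
  ev <- evaluate_detections(det, gt, 2)
  expect_equal(ev$map, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
})
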