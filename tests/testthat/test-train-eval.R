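# Training machinery: Wise-IoU properties, target assignment, smoke
# training, evaluation report schema, class activation maps.

test_that("training configuration defaults match the reference recipe", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 500L)
  expect_equal(cfg$batch, 8L)
  expect_equal(cfg$optimizer, "SGD")
  expect_equal(cfg$lr0, 1e-2)
  expect_equal(cfg$lrf, 1e-4)
  expect_equal(cfg$momentum, 0.937)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_equal(cfg$nms_iou, 0.7)
  expect_equal(cfg$wiou_alpha, 1.9)
  expect_equal(cfg$wiou_delta, 3)
  expect_equal(cfg$close_mosaic, 10L)
  expect_equal(cfg$image_size, 640L)
})

test_that("Wise-IoU: zero at a perfect match, neutral focusing at beta = delta", {
  b <- c(10, 10, 30, 40)
  expect_equal(wise_iou_loss(b, b), 0)
  # beta = delta = 3: the focusing factor r = beta/(delta*alpha^(beta-delta))
  # is exactly 1, so L = R * (1 - IoU)
  P <- c(0, 0, 2, 2); G <- c(1, 1, 3, 3)
  iou_pg <- 1 / 7
  rm <- (1 - iou_pg) / 3                 # forces beta = 3
  L <- wise_iou_loss(P, G, alpha = 1.9, delta = 3, running_mean = rm)
  R <- exp((1 + 1) / (3^2 + 3^2))        # centers (1,1) vs (2,2), enclosing 3x3
  expect_equal(L, R * (1 - iou_pg), tolerance = 1e-12)
  # hand-evaluated value with running mean equal to the current loss (beta = 1)
  rm2 <- 1 - iou_pg
  r2 <- 1 / (3 * 1.9^(1 - 3))
  expect_equal(wise_iou_loss(P, G, 1.9, 3, rm2), r2 * R * (1 - iou_pg),
               tolerance = 1e-12)
  # centers coincide and beta = delta: monotone decreasing in IoU
  losses <- sapply(c(0.2, 0.5, 0.8), function(s) {
    g <- c(50 - 10 * s, 50 - 10 * s, 50 + 10 * s, 50 + 10 * s)
    p <- c(40, 40, 60, 60)
    wise_iou_loss(p, g, running_mean = (1 - iou(p, g)) / 3)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("task-aligned assignment respects geometry", {
  set.seed(41)
  an <- serpensgate:::.make_anchors(list(c(8, 8)), 8)
  xy <- an$xy * an$stride
  A <- nrow(xy)
  pred_boxes <- cbind(xy[, 1] - 8, xy[, 2] - 8, xy[, 1] + 8, xy[, 2] + 8)
  scores <- matrix(0.5, A, 2)
  # single centered GT: every assigned anchor lies inside it
  gt <- matrix(c(16, 16, 48, 48), 1)
  asg <- assign_targets(xy, pred_boxes, scores, gt, 0L)
  expect_true(any(asg$fg))
  inside <- xy[asg$fg, 1] > 16 & xy[asg$fg, 1] < 48 &
    xy[asg$fg, 2] > 16 & xy[asg$fg, 2] < 48
  expect_true(all(inside))
  # no GT: no positives
  asg0 <- assign_targets(xy, pred_boxes, scores, NULL, integer(0))
  expect_false(any(asg0$fg))
  expect_equal(sum(asg0$cls_target), 0)
  # two disjoint GTs: center-inside keeps the anchor sets disjoint
  gt2 <- rbind(c(0, 0, 24, 24), c(40, 40, 64, 64))
  asg2 <- assign_targets(xy, pred_boxes, scores, gt2, c(0L, 1L))
  g1 <- which(asg2$fg & asg2$gt_idx == 1)
  g2 <- which(asg2$fg & asg2$gt_idx == 2)
  expect_gt(length(g1), 0)
  expect_gt(length(g2), 0)
  expect_length(intersect(g1, g2), 0)
  expect_true(all(xy[g1, 1] < 24) && all(xy[g2, 1] > 40))
})

test_that("the mosaic switch is off exactly for the final close_mosaic epochs", {
  cfg <- train_config(epochs = 30L, close_mosaic = 10L)
  on <- vapply(1:30, function(e) e <= cfg$epochs - cfg$close_mosaic, logical(1))
  expect_equal(sum(!on), 10)
  expect_false(any(on[21:30]))
  expect_true(all(on[1:20]))
})

make_tiny_dataset <- function(n, dir, seed = 3) {
  p <- synth_profile("desk")
  p$size <- 96L
  generate_dataset(n, dir, seed = seed, params = p)
}

test_that("one training epoch on a small synthetic set yields finite losses and identical re-runs", {
  d <- file.path(tempdir(), "train_smoke")
  unlink(d, recursive = TRUE)
  idx <- make_tiny_dataset(8, d)
  run <- function() {
    set.seed(77)
    m <- build_model(model_table(nc = 6, width = 0.25, reg_max = 4L))
    cfg <- train_config(epochs = 2L, batch = 4L, image_size = 96L, seed = 77,
                        close_mosaic = 1L, warmup_iters = 2L)
    res <- train_detector(m, idx$items, idx$items, 6, cfg, eval_every = 2L)
    res$log
  }
  log1 <- run()
  expect_true(all(is.finite(log1$total)))
  expect_true(all(log1$box >= 0 & log1$cls >= 0 & log1$dfl >= 0))
  expect_false(is.na(log1$map50[2]))
  log2 <- run()
  expect_equal(log1$total, log2$total, tolerance = 1e-12)
})

test_that("evaluation mirrors the headline report schema and an oracle scores 1", {
  d <- file.path(tempdir(), "eval_schema")
  unlink(d, recursive = TRUE)
  idx <- make_tiny_dataset(6, d, seed = 9)
  # oracle detections straight from the labels
  gt_all <- list()
  for (i in seq_len(nrow(idx$items))) {
    a <- read_yolo_labels(idx$items$label[i])
    if (nrow(a))
      gt_all[[length(gt_all) + 1]] <- data.frame(
        image = i, class = a$class,
        x1 = (a$cx - a$w / 2) * 96, y1 = (a$cy - a$h / 2) * 96,
        x2 = (a$cx + a$w / 2) * 96, y2 = (a$cy + a$h / 2) * 96)
  }
  gt <- do.call(rbind, gt_all)
  ev <- evaluate_model(NULL, idx$items, 6, size = 96L,
                       detections = oracle_detector(gt))
  expect_equal(names(ev$summary)[1:4],
               c("F1 Score", "Precision", "Recall", "mAP50"))
  expect_equal(ev$summary$mAP50, 1)
  expect_equal(ev$summary$Precision, 1)
  expect_equal(dim(ev$confusion), c(7, 7))
  expect_error(evaluate_model(NULL, idx$items[0, ], 6), "empty split")
})

test_that("class activation maps are normalized, image-sized and trace the score layer", {
  set.seed(55)
  m <- build_model(model_table(nc = 3, width = 0.25, reg_max = 4L))
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  # the best-scoring anchor may sit on any of the three scales; a scale whose
  # branch does not pass through the target layer yields the all-zero map
  cam <- suppressWarnings(grad_cam(m, img, target_layer = 8, class_id = 1))
  expect_equal(dim(cam), c(64, 64))
  expect_true(all(cam >= 0 & cam <= 1))
  expect_error(grad_cam(m, img, 22, 99), "invalid class")
})
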