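# Desk-scale training and evaluation: Wise-IoU box loss, task-aligned target
# assignment, DFL + BCE objectives, SGD with momentum and a linear learning
# rate decay, detection evaluation, and gradient-based class activation maps.

#' Training configuration
#'
#' Defaults follow the reference training recipe: 500 epochs, batch 8, SGD
#' with momentum 0.937 and weight decay 5e-4, learning rate decaying from
#' 1e-2 to 1e-4, NMS IoU 0.7, Wise-IoU alpha 1.9 and delta 3, and mosaic
#' augmentation disabled for the last 10 epochs.
#'
#' @param ... Overrides for any field.
#' @return A config list.
#' @export
train_config <- function(...) {
  cfg <- list(epochs = 500L, batch = 8L, optimizer = "SGD",
              lr0 = 1e-2, lrf = 1e-4, momentum = 0.937, weight_decay = 5e-4,
              nms_iou = 0.7, wiou_alpha = 1.9, wiou_delta = 3,
              close_mosaic = 10L, image_size = 640L, seed = 0L,
              conf_thr = 0.25, box_gain = 7.5, cls_gain = 0.5, dfl_gain = 1.5,
              flip_p = 0.5, translate = 0.1, scale_jitter = 0.5,
              warmup_iters = 50L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# ---- Wise-IoU ---------------------------------------------------------------

#' Wise-IoU bounding-box regression loss (scalar form)
#'
#' `L = r * R * (1 - IoU)` with the distance-attention term
#' `R = exp(((cx - cx')^2 + (cy - cy')^2) / (Wg^2 + Hg^2))` over the smallest
#' enclosing box (denominator treated as a constant), outlier degree
#' `beta = (1 - IoU) / running_mean` (running mean of `1 - IoU`, also
#' constant w.r.t. the gradient) and the focusing factor
#' `beta / (delta * alpha^(beta - delta))`, which is 1 at `beta = delta`.
#'
#' @param pred,target Pixel xyxy boxes.
#' @param alpha,delta Focusing hyperparameters (1.9 and 3 in the reference
#'   recipe).
#' @param running_mean Running mean of `1 - IoU` (the normalizer of the
#'   outlier degree).
#' @return The scalar loss.
#' @export
wise_iou_loss <- function(pred, target, alpha = 1.9, delta = 3,
                          running_mean = 1) {
  w <- .wiou_vec(matrix(pred, ncol = 4), matrix(target, ncol = 4),
                 alpha, delta, running_mean)
  w$loss[1]
}

# vectorized Wise-IoU with analytic gradients w.r.t. the predicted boxes
.wiou_vec <- function(P, G, alpha, delta, running_mean) {
  x1 <- P[, 1]; y1 <- P[, 2]; x2 <- P[, 3]; y2 <- P[, 4]
  gx1 <- G[, 1]; gy1 <- G[, 2]; gx2 <- G[, 3]; gy2 <- G[, 4]
  iw <- pmax(pmin(x2, gx2) - pmax(x1, gx1), 0)
  ih <- pmax(pmin(y2, gy2) - pmax(y1, gy1), 0)
  I <- iw * ih
  Ap <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  Ag <- (gx2 - gx1) * (gy2 - gy1)
  U <- pmax(Ap + Ag - I, 1e-9)
  iou <- I / U
  ew <- pmax(x2, gx2) - pmin(x1, gx1)
  eh <- pmax(y2, gy2) - pmin(y1, gy1)
  den <- ew^2 + eh^2
  bad <- den <= 0
  den[bad] <- 1
  cxp <- (x1 + x2) / 2; cyp <- (y1 + y2) / 2
  cxg <- (gx1 + gx2) / 2; cyg <- (gy1 + gy2) / 2
  num <- (cxp - cxg)^2 + (cyp - cyg)^2
  R <- exp(num / den)
  beta <- (1 - iou) / max(running_mean, 1e-6)
  r <- beta / (delta * alpha^(beta - delta))
  loss <- r * R * (1 - iou)
  loss[bad] <- 0
  # gradients (r, beta, den treated as constants)
  dI_dx1 <- ifelse(I > 0 & x1 > gx1, -ih, 0)
  dI_dx2 <- ifelse(I > 0 & x2 < gx2, ih, 0)
  dI_dy1 <- ifelse(I > 0 & y1 > gy1, -iw, 0)
  dI_dy2 <- ifelse(I > 0 & y2 < gy2, iw, 0)
  dAp_dx1 <- -(y2 - y1); dAp_dx2 <- y2 - y1
  dAp_dy1 <- -(x2 - x1); dAp_dy2 <- x2 - x1
  diou <- function(dI, dAp) (dI * U - I * (dAp - dI)) / U^2
  diou_dx1 <- diou(dI_dx1, dAp_dx1); diou_dx2 <- diou(dI_dx2, dAp_dx2)
  diou_dy1 <- diou(dI_dy1, dAp_dy1); diou_dy2 <- diou(dI_dy2, dAp_dy2)
  dnum_dx1 <- (cxp - cxg); dnum_dx2 <- (cxp - cxg)
  dnum_dy1 <- (cyp - cyg); dnum_dy2 <- (cyp - cyg)
  gfac <- r * R
  grad <- cbind(
    gfac * (dnum_dx1 / den * (1 - iou) - diou_dx1),
    gfac * (dnum_dy1 / den * (1 - iou) - diou_dy1),
    gfac * (dnum_dx2 / den * (1 - iou) - diou_dx2),
    gfac * (dnum_dy2 / den * (1 - iou) - diou_dy2)
  )
  grad[bad, ] <- 0
  list(loss = loss, grad = grad, iou = iou)
}

# ---- anchors, decoding ------------------------------------------------------

# anchor center points (grid units) and strides for a list of map sizes
.make_anchors <- function(sizes, strides) {
  pts <- list(); str <- list()
  for (s in seq_along(sizes)) {
    Hs <- sizes[[s]][1]; Ws <- sizes[[s]][2]
    # row-major over the map: anchor index = (y-1)*Ws + x
    xs <- rep(seq_len(Ws) - 0.5, times = Hs)
    ys <- rep(seq_len(Hs) - 0.5, each = Ws)
    pts[[s]] <- cbind(xs, ys)
    str[[s]] <- rep(strides[s], Hs * Ws)
  }
  list(xy = do.call(rbind, pts), stride = unlist(str))
}

# flatten one scale's raw map (H, W, C, N) to an A x C matrix for image n,
# anchor order row-major (matches .make_anchors)
.flatten_map <- function(x, n) {
  d <- dim(x)
  matrix(aperm(x[, , , n, drop = FALSE], c(2, 1, 3, 4)), d[1] * d[2], d[3])
}

# softmax over reg_max bins; dist: A x 4 expectations, P: list of prob mats
.decode_dfl <- function(B, reg_max) {
  A <- nrow(B)
  dist <- matrix(0, A, 4)
  probs <- vector("list", 4)
  proj <- 0:(reg_max - 1)
  for (sdx in 1:4) {
    L <- B[, (sdx - 1) * reg_max + seq_len(reg_max), drop = FALSE]
    Z <- exp(L - apply(L, 1, max))
    Pp <- Z / rowSums(Z)
    probs[[sdx]] <- Pp
    dist[, sdx] <- as.numeric(Pp %*% proj)
  }
  list(dist = dist, probs = probs)
}

# distances (l, t, r, b in grid units) -> pixel xyxy
.dist2box <- function(xy, dist, stride) {
  cbind((xy[, 1] - dist[, 1]) * stride, (xy[, 2] - dist[, 2]) * stride,
        (xy[, 1] + dist[, 3]) * stride, (xy[, 2] + dist[, 4]) * stride)
}

# ---- task-aligned assignment ------------------------------------------------

#' Task-aligned assignment of ground truths to anchors
#'
#' Candidate anchors must have their center inside the ground-truth box; the
#' top `k` candidates per ground truth by the alignment score
#' `cls^0.5 * IoU^6` are selected; an anchor claimed by several ground
#' truths goes to the one with the larger alignment. Class targets are the
#' alignment scores normalized per ground truth to its best IoU.
#'
#' @param anchor_xy `A x 2` anchor centers in pixels.
#' @param pred_boxes `A x 4` decoded pixel boxes.
#' @param pred_scores `A x nc` class probabilities (sigmoid).
#' @param gt_boxes `G x 4` pixel boxes.
#' @param gt_classes Length-`G` 0-based classes.
#' @param topk Candidates kept per ground truth.
#' @return List: `gt_idx` (length `A`, 0 = background), `cls_target`
#'   (`A x nc` soft targets), `fg` (positive mask).
#' @export
assign_targets <- function(anchor_xy, pred_boxes, pred_scores, gt_boxes,
                           gt_classes, topk = 10L) {
  A <- nrow(anchor_xy)
  nc <- ncol(pred_scores)
  gt_idx <- integer(A)
  cls_target <- matrix(0, A, nc)
  G <- if (is.null(gt_boxes) || length(gt_boxes) == 0) 0L else nrow(gt_boxes)
  if (G == 0)
    return(list(gt_idx = gt_idx, cls_target = cls_target, fg = logical(A)))
  align <- matrix(0, A, G)
  ious <- matrix(0, A, G)
  for (g in seq_len(G)) {
    inside <- anchor_xy[, 1] > gt_boxes[g, 1] & anchor_xy[, 1] < gt_boxes[g, 3] &
      anchor_xy[, 2] > gt_boxes[g, 2] & anchor_xy[, 2] < gt_boxes[g, 4]
    if (!any(inside)) next
    iog <- iou_one_many(gt_boxes[g, ], pred_boxes[inside, , drop = FALSE])
    ious[inside, g] <- iog
    sc <- pred_scores[inside, gt_classes[g] + 1L]
    al <- sqrt(pmax(sc, 0)) * pmax(iog, 0)^6
    # top-k candidates for this ground truth
    cand <- which(inside)
    if (length(cand) > topk) {
      keep <- cand[order(al, decreasing = TRUE)[seq_len(topk)]]
      al_keep <- al[order(al, decreasing = TRUE)[seq_len(topk)]]
      align[keep, g] <- al_keep
    } else {
      align[cand, g] <- al
    }
  }
  best_g <- max.col(align, ties.method = "first")
  best_a <- align[cbind(seq_len(A), best_g)]
  fg <- best_a > 0
  gt_idx[fg] <- best_g[fg]
  # normalize: per GT, target = align / max_align * max_iou
  for (g in seq_len(G)) {
    sel <- which(fg & gt_idx == g)
    if (!length(sel)) next
    mx_al <- max(align[sel, g])
    mx_iou <- max(ious[sel, g])
    cls_target[sel, gt_classes[g] + 1L] <-
      align[sel, g] / max(mx_al, 1e-9) * mx_iou
  }
  list(gt_idx = gt_idx, cls_target = cls_target, fg = fg)
}

# ---- loss -------------------------------------------------------------------

# loss and gradient w.r.t. the raw head outputs for one batch.
# outs: detect raw maps; gts: list per image of data frames (pixel frame).
# Returns loss breakdown and the gradient structure for sg_backward.
detect_loss <- function(model, outs, gts, img_size, cfg, state) {
  reg_max <- model$reg_max
  nc <- model$nc
  sizes <- lapply(outs, function(o) dim(o$box)[1:2])
  N <- dim(outs[[1]]$box)[4]
  an <- .make_anchors(sizes, model$export_strides)
  A <- nrow(an$xy)
  nper <- vapply(sizes, function(s) s[1] * s[2], numeric(1))
  scale_of <- rep(seq_along(sizes), nper)
  gbox_flat <- lapply(seq_along(sizes), function(s)
    array(0, dim = c(sizes[[s]][1], sizes[[s]][2], 4 * reg_max, N)))
  gcls_flat <- lapply(seq_along(sizes), function(s)
    array(0, dim = c(sizes[[s]][1], sizes[[s]][2], nc, N)))
  loss_box <- loss_cls <- loss_dfl <- 0
  iou_batch <- numeric(0)
  for (n in seq_len(N)) {
    B <- do.call(rbind, lapply(outs, function(o) .flatten_map(o$box, n)))
    CL <- do.call(rbind, lapply(outs, function(o) .flatten_map(o$cls, n)))
    dd <- .decode_dfl(B, reg_max)
    pix_xy <- an$xy * an$stride
    pbox <- .dist2box(an$xy, dd$dist, an$stride)
    scores <- 1 / (1 + exp(-CL))
    g <- gts[[n]]
    gt_boxes <- if (nrow(g)) as.matrix(g[, c("x1", "y1", "x2", "y2")]) else NULL
    asg <- assign_targets(pix_xy, pbox, scores, gt_boxes, g$class)
    Tgt <- asg$cls_target
    norm <- max(sum(Tgt), 1)
    # classification BCE (sum over anchors and classes, / norm)
    eps <- 1e-9
    loss_cls <- loss_cls +
      -sum(Tgt * log(scores + eps) + (1 - Tgt) * log(1 - scores + eps)) / norm
    dCL <- (scores - Tgt) / norm
    fg <- which(asg$fg)
    dB <- matrix(0, A, 4 * reg_max)
    if (length(fg)) {
      gi <- asg$gt_idx[fg]
      Gm <- gt_boxes[gi, , drop = FALSE]
      w <- Tgt[cbind(fg, g$class[gi] + 1L)]
      wv <- .wiou_vec(pbox[fg, , drop = FALSE], Gm, cfg$wiou_alpha,
                      cfg$wiou_delta, state$wiou_mean)
      iou_batch <- c(iou_batch, wv$iou)
      loss_box <- loss_box + sum(wv$loss * w) / norm
      dxyxy <- wv$grad * w / norm
      # chain to distances: x1 = (ax - l) s, y1 = (ay - t) s,
      # x2 = (ax + r) s, y2 = (ay + b) s
      sfg <- an$stride[fg]
      ddist <- cbind(-dxyxy[, 1] * sfg, -dxyxy[, 2] * sfg,
                     dxyxy[, 3] * sfg, dxyxy[, 4] * sfg)
      # DFL cross-entropy toward the true distances
      tdist <- cbind((pix_xy[fg, 1] - Gm[, 1]) / sfg,
                     (pix_xy[fg, 2] - Gm[, 2]) / sfg,
                     (Gm[, 3] - pix_xy[fg, 1]) / sfg,
                     (Gm[, 4] - pix_xy[fg, 2]) / sfg)
      tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 1e-3)
      for (sdx in 1:4) {
        Pp <- dd$probs[[sdx]][fg, , drop = FALSE]
        td <- tdist[, sdx]
        lo <- floor(td); hi <- lo + 1
        wl <- hi - td; wh <- td - lo
        pl <- Pp[cbind(seq_along(fg), lo + 1L)]
        ph <- Pp[cbind(seq_along(fg), pmin(hi, reg_max - 1) + 1L)]
        loss_dfl <- loss_dfl +
          sum((-wl * log(pl + eps) - wh * log(ph + eps)) * w) / norm
        # gradient of CE through the softmax, plus the expectation chain
        Tm <- matrix(0, length(fg), reg_max)
        Tm[cbind(seq_along(fg), lo + 1L)] <- wl
        Tm[cbind(seq_along(fg), pmin(hi, reg_max - 1) + 1L)] <-
          Tm[cbind(seq_along(fg), pmin(hi, reg_max - 1) + 1L)] + wh
        gce <- (Pp - Tm) * (w / norm) * cfg$dfl_gain
        # expectation backward: ddist -> dlogits
        proj <- matrix(0:(reg_max - 1), length(fg), reg_max, byrow = TRUE)
        dv <- ddist[, sdx] * cfg$box_gain
        gexp <- Pp * (proj - rowSums(Pp * proj)) * dv
        dB[fg, (sdx - 1) * reg_max + seq_len(reg_max)] <-
          dB[fg, (sdx - 1) * reg_max + seq_len(reg_max)] + gce + gexp
      }
    }
    dCL <- dCL * cfg$cls_gain
    # scatter flat gradients back to per-scale maps
    at <- 0
    for (s in seq_along(sizes)) {
      idx <- at + seq_len(nper[s])
      Hs <- sizes[[s]][1]; Ws <- sizes[[s]][2]
      gbox_flat[[s]][, , , n] <-
        aperm(array(dB[idx, , drop = FALSE], dim = c(Ws, Hs, 4 * reg_max)),
              c(2, 1, 3))
      gcls_flat[[s]][, , , n] <-
        aperm(array(dCL[idx, , drop = FALSE], dim = c(Ws, Hs, nc)), c(2, 1, 3))
      at <- at + nper[s]
    }
  }
  if (length(iou_batch))
    state$wiou_mean <- 0.95 * state$wiou_mean + 0.05 * mean(1 - iou_batch)
  grads <- lapply(seq_along(sizes), function(s)
    list(box = gbox_flat[[s]], cls = gcls_flat[[s]]))
  list(box = cfg$box_gain * loss_box / N, cls = cfg$cls_gain * loss_cls / N,
       dfl = cfg$dfl_gain * loss_dfl / N,
       total = (cfg$box_gain * loss_box + cfg$cls_gain * loss_cls +
                  cfg$dfl_gain * loss_dfl) / N,
       grads = lapply(grads, function(g) list(box = g$box / N, cls = g$cls / N)))
}

# ---- optimizer --------------------------------------------------------------

sgd_step <- function(model, lr, momentum, weight_decay, state) {
  ps <- sg_parameters(model)
  if (is.null(state$velocity)) state$velocity <- vector("list", length(ps))
  for (i in seq_along(ps)) {
    p <- ps[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0 && length(dim(p$value)) > 1) g <- g + weight_decay * p$value
    v <- state$velocity[[i]]
    v <- if (is.null(v)) g else momentum * v + g
    state$velocity[[i]] <- v
    p$value <- p$value - lr * v
  }
  sg_zero_grad(model)
  invisible(state)
}

# ---- prediction & evaluation ------------------------------------------------

#' Run the detector on one image
#'
#' Letterboxes to `size`, runs the network, decodes the DFL distributions,
#' filters by confidence and applies class-wise NMS.
#'
#' @param model Assembled `sg_model`.
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param size Canvas side (divisible by 32).
#' @param conf_thr Minimum class confidence.
#' @param nms_iou NMS threshold (0.7 in the reference recipe).
#' @return Data frame `class, score, x1, y1, x2, y2` in canvas pixels, plus
#'   the letterbox transform as attribute `"transform"`.
#' @export
predict_image <- function(model, img, size = 640L, conf_thr = 0.25,
                          nms_iou = 0.7) {
  lb <- letterbox(img, size)
  x <- array(lb$image, dim = c(size, size, 3, 1))
  outs <- sg_forward(model, x, train = FALSE)
  sizes <- lapply(outs, function(o) dim(o$box)[1:2])
  an <- .make_anchors(sizes, model$export_strides)
  B <- do.call(rbind, lapply(outs, function(o) .flatten_map(o$box, 1)))
  CL <- do.call(rbind, lapply(outs, function(o) .flatten_map(o$cls, 1)))
  dd <- .decode_dfl(B, model$reg_max)
  pbox <- .dist2box(an$xy, dd$dist, an$stride)
  scores <- 1 / (1 + exp(-CL))
  best <- max.col(scores, ties.method = "first")
  conf <- scores[cbind(seq_len(nrow(scores)), best)]
  keep <- which(conf >= conf_thr)
  out <- data.frame(class = integer(0), score = numeric(0), x1 = numeric(0),
                    y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  if (length(keep)) {
    kb <- pbox[keep, , drop = FALSE]
    ki <- nms(kb, conf[keep], nms_iou, classes = best[keep])
    out <- data.frame(class = best[keep][ki] - 1L, score = conf[keep][ki],
                      x1 = kb[ki, 1], y1 = kb[ki, 2],
                      x2 = kb[ki, 3], y2 = kb[ki, 4])
  }
  attr(out, "transform") <- lb$transform
  out
}

#' Evaluate a model on a dataset split
#'
#' Runs prediction on every item, compares against the YOLO labels in the
#' letterboxed canvas frame, and reports the four headline fields (F1,
#' precision, recall, mAP@0.5) plus per-class rows and a confusion matrix.
#'
#' @param model Assembled `sg_model`.
#' @param items Data frame with `image`, `label` paths.
#' @param n_classes Number of classes.
#' @param size Canvas side.
#' @param conf_thr,nms_iou Operating point.
#' @param detections Optional precomputed detection data frame (bypasses the
#'   model, e.g. for an oracle check).
#' @return List: `summary` (F1 / precision / recall / mAP@0.5, plus a
#'   macro-averaged F1), `per_class`, `confusion`.
#' @export
evaluate_model <- function(model, items, n_classes, size = 256L,
                           conf_thr = 0.25, nms_iou = 0.7,
                           detections = NULL) {
  if (nrow(items) == 0) stop("evaluation error: empty split")
  gt_all <- list(); det_all <- list()
  for (i in seq_len(nrow(items))) {
    img <- read_image(items$image[i])
    ann <- read_yolo_labels(items$label[i])
    lb_tr <- letterbox(img, size)$transform
    a <- apply_letterbox(ann, lb_tr)
    if (nrow(a))
      gt_all[[length(gt_all) + 1]] <- data.frame(
        image = i, class = a$class,
        x1 = (a$cx - a$w / 2) * size, y1 = (a$cy - a$h / 2) * size,
        x2 = (a$cx + a$w / 2) * size, y2 = (a$cy + a$h / 2) * size)
    if (is.null(detections)) {
      d <- predict_image(model, img, size, conf_thr = 0.001, nms_iou = nms_iou)
      if (nrow(d)) {
        d$image <- i
        det_all[[length(det_all) + 1]] <- d
      }
    }
  }
  gt <- if (length(gt_all)) do.call(rbind, gt_all) else
    data.frame(image = integer(0), class = integer(0), x1 = numeric(0),
               y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  det <- if (!is.null(detections)) detections else
    if (length(det_all)) do.call(rbind, det_all) else
      data.frame(image = integer(0), class = integer(0), score = numeric(0),
                 x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0))
  ev <- evaluate_detections(det, gt, n_classes, iou_thr = 0.5,
                            conf_thr = conf_thr)
  cm <- confusion_matrix(det, gt, n_classes, conf_thr = conf_thr)
  list(summary = data.frame(`F1 Score` = ev$f1, Precision = ev$precision,
                            Recall = ev$recall, mAP50 = ev$map,
                            F1_macro = ev$f1_macro, check.names = FALSE),
       per_class = ev$per_class, confusion = cm, ap = ev$ap)
}

# ---- training loop ----------------------------------------------------------

.load_item <- function(items, i) {
  list(image = read_image(items$image[i]), ann = read_yolo_labels(items$label[i]))
}

# preload a whole split into memory (desk-scale datasets are small)
.load_all <- function(items) {
  lapply(seq_len(nrow(items)), function(i) suppressWarnings(.load_item(items, i)))
}

#' Train the detector
#'
#' SGD with momentum and weight decay; the learning rate decays linearly
#' from `lr0` to `lrf` (with a short linear warmup); mosaic augmentation is
#' on except for the final `close_mosaic` epochs; everything is seeded, so a
#' single-threaded run is reproducible. Aborts with a diagnostic on
#' divergence (non-finite loss). The checkpoint with the best validation
#' mAP@0.5 is kept.
#'
#' @param model Assembled `sg_model` (modified in place; the returned log
#'   and best weights come with it).
#' @param train_items,val_items Data frames with `image`, `label` paths.
#' @param n_classes Number of classes.
#' @param cfg A [train_config()].
#' @param eval_every Validate every this many epochs (and at the end).
#' @param verbose Print per-epoch lines.
#' @return List: `log` (per-epoch data frame), `best_map`, `best_epoch`;
#'   the model carries the best weights.
#' @export
train_detector <- function(model, train_items, val_items, n_classes,
                           cfg = train_config(), eval_every = 5L,
                           verbose = FALSE) {
  if (nrow(train_items) == 0) stop("training error: empty dataset")
  set.seed(cfg$seed)
  state <- new.env(parent = emptyenv())
  state$wiou_mean <- 1
  cache <- .load_all(train_items)
  nb <- max(1, floor(nrow(train_items) / cfg$batch))
  total_iters <- cfg$epochs * nb
  it <- 0
  log <- list()
  best_map <- -Inf; best_epoch <- 0L; best_weights <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    mosaic_on <- epoch <= cfg$epochs - cfg$close_mosaic
    ord <- sample.int(nrow(train_items))
    ep_loss <- c(box = 0, cls = 0, dfl = 0, total = 0)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch + 1):min(b * cfg$batch, nrow(train_items))]
      imgs <- array(0, dim = c(cfg$image_size, cfg$image_size, 3, length(idx)))
      gts <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        picks <- c(idx[j], sample.int(nrow(train_items), 3, replace = TRUE))
        samp <- mosaic_augment(cache[picks],
                               seed = cfg$seed * 100000 + epoch * 1000 + b * 10 + j,
                               enabled = mosaic_on, target = cfg$image_size,
                               flip_p = cfg$flip_p, translate = cfg$translate,
                               scale_jitter = cfg$scale_jitter)
        imgs[, , , j] <- samp$image
        a <- samp$ann
        gts[[j]] <- data.frame(
          class = a$class,
          x1 = (a$cx - a$w / 2) * cfg$image_size,
          y1 = (a$cy - a$h / 2) * cfg$image_size,
          x2 = (a$cx + a$w / 2) * cfg$image_size,
          y2 = (a$cy + a$h / 2) * cfg$image_size)
      }
      outs <- sg_forward(model, imgs, train = TRUE)
      ls <- detect_loss(model, outs, gts, cfg$image_size, cfg, state)
      if (!is.finite(ls$total))
        stop(sprintf("divergence: non-finite loss at epoch %d batch %d (box %.3g cls %.3g dfl %.3g)",
                     epoch, b, ls$box, ls$cls, ls$dfl))
      sg_backward(model, ls$grads)
      it <- it + 1
      frac <- it / total_iters
      lr <- cfg$lr0 * (1 - frac) + cfg$lrf * frac
      if (it <= cfg$warmup_iters) lr <- lr * it / cfg$warmup_iters
      sgd_step(model, lr, cfg$momentum, cfg$weight_decay, state)
      ep_loss <- ep_loss + c(ls$box, ls$cls, ls$dfl, ls$total)
    }
    ep_loss <- ep_loss / nb
    row <- data.frame(epoch = epoch, box = ep_loss[1], cls = ep_loss[2],
                      dfl = ep_loss[3], total = ep_loss[4], map50 = NA_real_)
    if (epoch %% eval_every == 0 || epoch == cfg$epochs) {
      ev <- evaluate_model(model, val_items, n_classes, size = cfg$image_size,
                           conf_thr = cfg$conf_thr, nms_iou = cfg$nms_iou)
      row$map50 <- ev$summary$mAP50
      if (is.finite(row$map50) && row$map50 > best_map) {
        best_map <- row$map50
        best_epoch <- epoch
        best_weights <- get_weights(model)
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f (box %.4f cls %.4f dfl %.4f)  mAP50 %s",
                      epoch, row$total, row$box, row$cls, row$dfl,
                      ifelse(is.na(row$map50), "-", sprintf("%.3f", row$map50))))
    log[[epoch]] <- row
  }
  if (!is.null(best_weights)) set_weights(model, best_weights)
  list(log = do.call(rbind, log), best_map = best_map, best_epoch = best_epoch)
}

#' Get / set model weights as a plain list
#'
#' @param model Assembled `sg_model`.
#' @return `get_weights` returns a named list of arrays (plus batch-norm
#'   running statistics).
#' @export
get_weights <- function(model) {
  ps <- sg_parameters(model)
  w <- lapply(ps, function(p) p$value)
  w$.running <- .collect_running(model)
  w
}

#' @rdname get_weights
#' @param weights A list from [get_weights()].
#' @export
set_weights <- function(model, weights) {
  ps <- sg_parameters(model)
  for (nm in names(ps)) ps[[nm]]$value <- weights[[nm]]
  .restore_running(model, weights$.running)
  invisible(model)
}

.collect_running <- function(m) {
  out <- list()
  if (!is.null(m$running_mean)) out$self <- list(mean = m$running_mean, var = m$running_var)
  for (nm in names(m$modules)) {
    sub <- .collect_running(m$modules[[nm]])
    if (length(sub)) for (snm in names(sub)) out[[paste0(nm, ".", snm)]] <- sub[[snm]]
  }
  out
}

.restore_running <- function(m, run, prefix = "") {
  if (is.null(run)) return(invisible(m))
  if (!is.null(m$running_mean) && !is.null(run[["self"]])) {
    m$running_mean <- run$self$mean; m$running_var <- run$self$var
  }
  for (nm in names(m$modules)) {
    keys <- names(run)[startsWith(names(run), paste0(nm, "."))]
    sub <- run[keys]
    names(sub) <- substring(keys, nchar(nm) + 2)
    .restore_running(m$modules[[nm]], sub)
  }
  invisible(m)
}

# ---- Grad-CAM ---------------------------------------------------------------

#' Gradient-weighted class activation map
#'
#' Backpropagates the best class confidence score for `class_id` to the
#' chosen layer, averages the gradient spatially into per-channel weights,
#' and returns the rectified weighted activation sum, min-max normalized and
#' upsampled to the image size. All-zero gradients yield an all-zero map
#' with a warning.
#'
#' @param model Assembled `sg_model`.
#' @param img `H x W x 3` image in `[0, 1]` (square, side divisible by 32).
#' @param target_layer 0-based layer index whose activations are explained.
#' @param class_id 0-based class.
#' @return Heatmap matrix (image size) with values in `[0, 1]`.
#' @export
grad_cam <- function(model, img, target_layer, class_id) {
  size <- dim(img)[1]
  x <- array(img, dim = c(size, size, 3, 1))
  outs <- sg_forward(model, x, train = TRUE)
  acts <- model$last_outputs
  if (class_id < 0 || class_id >= model$nc) stop("invalid class id")
  # pick the anchor with the highest confidence for the class
  best <- list(score = -Inf)
  for (s in seq_along(outs)) {
    CL <- .flatten_map(outs[[s]]$cls, 1)
    sc <- 1 / (1 + exp(-CL[, class_id + 1L]))
    j <- which.max(sc)
    if (sc[j] > best$score) best <- list(score = sc[j], scale = s, anchor = j)
  }
  # gradient of the confidence at that single logit
  gy <- lapply(outs, function(o)
    list(box = array(0, dim = dim(o$box)), cls = array(0, dim = dim(o$cls))))
  d <- dim(outs[[best$scale]]$cls)
  Ws <- d[2]
  ay <- (best$anchor - 1L) %/% Ws + 1L
  ax <- (best$anchor - 1L) %% Ws + 1L
  gy[[best$scale]]$cls[ay, ax, class_id + 1L, 1] <- best$score * (1 - best$score)
  # manual reverse sweep collecting the gradient entering the target layer
  grads <- vector("list", model$n_layers)
  grads[[model$n_layers]] <- gy
  target_grad <- NULL
  for (i in rev(seq_len(model$n_layers))) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (i - 1L == target_layer) { target_grad <- g; break }
    from <- model$sources[[i]]
    gin <- sg_backward(model$modules[[paste0("l", i - 1L)]], g)
    if (i == 1) break
    if (length(from) == 1L) gin <- list(gin)
    for (k in seq_along(from)) {
      j <- from[k] + 1L
      grads[[j]] <- if (is.null(grads[[j]])) gin[[k]] else grads[[j]] + gin[[k]]
    }
  }
  sg_zero_grad(model)
  if (is.null(target_grad)) stop("target layer received no gradient")
  act <- acts[[target_layer + 1L]]
  wts <- apply(target_grad[, , , 1, drop = FALSE], 3, mean)
  if (all(wts == 0)) {
    warning("all-zero gradient at the target layer; returning an empty map")
    return(matrix(0, size, size))
  }
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (ch in seq_along(wts)) cam <- cam + wts[ch] * act[, , ch, 1]
  cam <- pmax(cam, 0)
  if (max(cam) > min(cam)) cam <- (cam - min(cam)) / (max(cam) - min(cam))
  resize_image(array(cam, dim = c(dim(cam), 1)), size, size)[, , 1]
}
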