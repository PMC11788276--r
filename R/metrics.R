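# Detection evaluation: IoU, greedy NMS, precision/recall/F1, per-class
# average precision with all-point interpolation, mAP@0.5, confusion matrix.
#
# Boxes are pixel xyxy vectors c(x1, y1, x2, y2) or n x 4 matrices.
# Internal precision/recall values live in [0, 1]; the percent scaling of the
# usual display convention is left to the caller.

#' Intersection over union of two pixel boxes
#'
#' @param a,b Boxes `c(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`.
#' @return IoU in `[0, 1]`; a degenerate box yields 0 with a warning.
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    warning("degenerate box in iou(); returning 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# vectorized IoU of one box against an n x 4 matrix
iou_one_many <- function(a, B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 4)
  iw <- pmin(a[3], B[, 3]) - pmax(a[1], B[, 1])
  ih <- pmin(a[4], B[, 4]) - pmax(a[2], B[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter)
}

#' Greedy non-maximum suppression
#'
#' Descending-score greedy suppression at `iou_thr`; when `classes` is given
#' the suppression is class-wise (boxes of different classes never suppress
#' each other).
#'
#' @param boxes `n x 4` xyxy matrix.
#' @param scores Length-`n` confidences.
#' @param iou_thr Suppression threshold (0.7 in the reference configuration).
#' @param classes Optional length-`n` integer class ids.
#' @return Indices of kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thr = 0.7, classes = NULL) {
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4)
  n <- nrow(boxes)
  if (n != length(scores)) stop("nms: boxes and scores length mismatch")
  if (n == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    ious <- iou_one_many(boxes[i, ], boxes)
    kill <- ious > iou_thr
    if (!is.null(classes)) kill <- kill & classes == classes[i]
    kill[i] <- FALSE
    alive[kill] <- FALSE
  }
  keep
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any zero
#' denominator yields 0 by convention.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Named vector `c(precision, recall, f1)` in `[0, 1]`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# greedy confidence-ordered matching of one class' detections to ground
# truths; each GT matchable once. det: n x 5 (x1,y1,x2,y2,score); gt: m x 4.
match_detections <- function(det, gt, iou_thr = 0.5) {
  nd <- if (is.null(dim(det))) as.integer(length(det) > 0) else nrow(det)
  if (nd > 0 && is.null(dim(det))) det <- matrix(det, ncol = 5)
  ng <- if (is.null(gt) || length(gt) == 0) 0L
        else { if (is.null(dim(gt))) gt <- matrix(gt, ncol = 4); nrow(gt) }
  tp <- logical(nd)
  if (nd == 0) return(list(tp = tp, scores = numeric(0), n_gt = ng))
  ord <- order(det[, 5], decreasing = TRUE)
  used <- logical(ng)
  for (i in ord) {
    if (ng == 0) break
    ious <- iou_one_many(det[i, 1:4], gt)
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(tp = tp[ord], scores = det[ord, 5], n_gt = ng)
}

#' Average precision for one class
#'
#' Area under the precision-recall envelope with all-point interpolation:
#' precision is made monotone non-increasing from the right, then integrated
#' as a step function over recall.
#'
#' @param tp Logical vector of per-detection hit flags, in descending
#'   confidence order.
#' @param n_gt Number of ground-truth objects of the class.
#' @return AP in `[0, 1]`; `NA` when there are neither ground truths nor
#'   detections (undefined, excluded from the mean).
#' @export
average_precision <- function(tp, n_gt) {
  if (n_gt == 0 && length(tp) == 0) return(NA_real_)
  if (n_gt == 0) return(0)
  if (length(tp) == 0) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  r <- c(0, recall, 1)
  p <- c(1, precision, 0)
  for (i in (length(p) - 1):1) p[i] <- max(p[i], p[i + 1])
  idx <- which(r[-1] != r[-length(r)])
  sum((r[idx + 1] - r[idx]) * p[idx + 1])
}

#' Mean average precision over classes
#'
#' The arithmetic mean of the defined per-class AP values; classes absent
#' from both ground truth and predictions (AP undefined) are excluded.
#'
#' @param ap_per_class Numeric vector of per-class APs (may contain `NA`).
#' @return Scalar mAP.
#' @export
mean_ap <- function(ap_per_class) {
  ok <- !is.na(ap_per_class)
  if (!any(ok)) stop("mean_ap: no class with a defined AP")
  mean(ap_per_class[ok])
}

#' Evaluate detections against ground truths
#'
#' Pools detections over images, matches greedily by confidence at
#' `iou_thr`, and returns per-class AP, mAP@`iou_thr`, and pooled
#' precision/recall/F1 at `conf_thr` plus a macro-averaged F1 over classes.
#'
#' @param detections Data frame with columns `image`, `class`, `x1`, `y1`,
#'   `x2`, `y2`, `score`.
#' @param ground_truths Data frame with columns `image`, `class`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @param n_classes Number of classes (ids `0 ... n_classes - 1`).
#' @param iou_thr Match threshold (0.5 for mAP@0.5).
#' @param conf_thr Confidence threshold for the P/R/F1 operating point.
#' @return List: `ap` (per class), `map`, `precision`, `recall`, `f1`
#'   (pooled), `f1_macro`, and the per-class table.
#' @export
evaluate_detections <- function(detections, ground_truths, n_classes,
                                iou_thr = 0.5, conf_thr = 0.25) {
  ap <- rep(NA_real_, n_classes)
  cls_rows <- vector("list", n_classes)
  tp_tot <- fp_tot <- fn_tot <- 0
  f1s <- numeric(0)
  for (k in seq_len(n_classes) - 1L) {
    dk <- detections[detections$class == k, , drop = FALSE]
    tps <- logical(0); scs <- numeric(0); ngt <- 0L
    tpc <- fpc <- fnc <- 0L
    imgs <- union(unique(dk$image),
                  unique(ground_truths$image[ground_truths$class == k]))
    for (im in imgs) {
      d <- dk[dk$image == im, , drop = FALSE]
      g <- ground_truths[ground_truths$image == im & ground_truths$class == k,
                         c("x1", "y1", "x2", "y2"), drop = FALSE]
      mm <- match_detections(as.matrix(d[, c("x1", "y1", "x2", "y2", "score")]),
                             as.matrix(g), iou_thr)
      tps <- c(tps, mm$tp); scs <- c(scs, mm$scores); ngt <- ngt + mm$n_gt
      # operating point at conf_thr
      dc <- d[d$score >= conf_thr, , drop = FALSE]
      mc <- match_detections(as.matrix(dc[, c("x1", "y1", "x2", "y2", "score")]),
                             as.matrix(g), iou_thr)
      tpc <- tpc + sum(mc$tp); fpc <- fpc + sum(!mc$tp)
      fnc <- fnc + (mc$n_gt - sum(mc$tp))
    }
    ord <- order(scs, decreasing = TRUE)
    ap[k + 1L] <- if (ngt == 0 && length(tps) == 0) NA_real_
                  else average_precision(tps[ord], ngt)
    tp_tot <- tp_tot + tpc; fp_tot <- fp_tot + fpc; fn_tot <- fn_tot + fnc
    prf <- precision_recall_f1(tpc, fpc, fnc)
    if (ngt > 0 || tpc + fpc > 0) f1s <- c(f1s, prf[["f1"]])
    cls_rows[[k + 1L]] <- data.frame(class = k, n_gt = ngt,
                                     precision = prf[["precision"]],
                                     recall = prf[["recall"]],
                                     f1 = prf[["f1"]], ap50 = ap[k + 1L])
  }
  pooled <- precision_recall_f1(tp_tot, fp_tot, fn_tot)
  list(ap = ap, map = mean_ap(ap),
       precision = pooled[["precision"]], recall = pooled[["recall"]],
       f1 = pooled[["f1"]],
       f1_macro = if (length(f1s)) mean(f1s) else 0,
       per_class = do.call(rbind, cls_rows))
}

#' Detection confusion matrix
#'
#' `(C+1) x (C+1)` counts with the extra row/column for background: rows are
#' true classes, columns predicted. Detections below `conf_thr` are dropped;
#' remaining detections are matched to ground truths greedily by IoU;
#' unmatched ground truths count as (true class, background) and unmatched
#' detections as (background, predicted class).
#'
#' @param detections,ground_truths Data frames as in
#'   [evaluate_detections()], single image or with an `image` column.
#' @param n_classes Number of real classes.
#' @param iou_thr IoU match threshold.
#' @param conf_thr Confidence threshold.
#' @return Integer matrix with dimnames including `"background"`.
#' @export
confusion_matrix <- function(detections, ground_truths, n_classes,
                             iou_thr = 0.5, conf_thr = 0.25) {
  cm <- matrix(0L, n_classes + 1L, n_classes + 1L)
  nms_cls <- c(paste0("class", seq_len(n_classes) - 1L), "background")
  dimnames(cm) <- list(true = nms_cls, pred = nms_cls)
  if (!"image" %in% names(detections)) detections$image <- 1L
  if (!"image" %in% names(ground_truths)) ground_truths$image <- 1L
  for (im in union(unique(detections$image), unique(ground_truths$image))) {
    d <- detections[detections$image == im & detections$score >= conf_thr, ,
                    drop = FALSE]
    g <- ground_truths[ground_truths$image == im, , drop = FALSE]
    used_g <- logical(nrow(g))
    if (nrow(d)) {
      for (i in order(d$score, decreasing = TRUE)) {
        best <- 0; bj <- 0L
        if (nrow(g)) {
          ious <- iou_one_many(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                               as.matrix(g[, c("x1", "y1", "x2", "y2")]))
          ious[used_g] <- -1
          bj <- which.max(ious); best <- ious[bj]
        }
        if (bj > 0 && best >= iou_thr) {
          used_g[bj] <- TRUE
          cm[g$class[bj] + 1L, d$class[i] + 1L] <- cm[g$class[bj] + 1L, d$class[i] + 1L] + 1L
        } else {
          cm[n_classes + 1L, d$class[i] + 1L] <- cm[n_classes + 1L, d$class[i] + 1L] + 1L
        }
      }
    }
    if (any(!used_g))
      for (j in which(!used_g))
        cm[g$class[j] + 1L, n_classes + 1L] <- cm[g$class[j] + 1L, n_classes + 1L] + 1L
  }
  cm
}
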