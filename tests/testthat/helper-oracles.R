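# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# scalar per-pixel bilinear interpolation (loop form)
oracle_bilinear <- function(feat, yy, xx) {
  H <- nrow(feat); W <- ncol(feat)
  y0 <- floor(yy); x0 <- floor(xx)
  y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
  fy <- yy - y0; fx <- xx - x0
  (1 - fy) * (1 - fx) * feat[y0 + 1, x0 + 1] +
    (1 - fy) * fx * feat[y0 + 1, x1 + 1] +
    fy * (1 - fx) * feat[y1 + 1, x0 + 1] +
    fy * fx * feat[y1 + 1, x1 + 1]
}

# direct dense 2-D cross-correlation with zero padding (the convolution the
# network computes), looped per output pixel
oracle_conv2d <- function(x, w, stride = 1, pad = NULL) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  if (is.null(pad)) pad <- c(kh %/% 2, kw %/% 2)
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad[1] - kh) %/% stride + 1
  Wo <- (W + 2 * pad[2] - kw) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, Cout))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- 0
    for (ci in 1:Cin) for (ik in 1:kh) for (jk in 1:kw) {
      hi <- (ho - 1) * stride - pad[1] + ik
      wi <- (wo - 1) * stride - pad[2] + jk
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci] * w[ik, jk, ci, co]
    }
    out[ho, wo, co] <- acc
  }
  out
}

# O(n^2) brute-force greedy NMS
oracle_nms <- function(boxes, scores, thr, classes = NULL) {
  n <- nrow(boxes)
  ord <- order(scores, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (!is.null(classes) && classes[i] != classes[j]) next
      if (iou(boxes[i, ], boxes[j, ]) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# step-sum AP over an explicit PR curve (monotone envelope, no shortcuts)
oracle_ap <- function(tp, n_gt) {
  if (n_gt == 0) return(if (length(tp) == 0) NA_real_ else 0)
  if (length(tp) == 0) return(0)
  rec <- cumsum(tp) / n_gt
  prec <- cumsum(tp) / seq_along(tp)
  area <- 0
  prev_r <- 0
  for (i in seq_along(tp)) {
    # envelope: best precision at any recall >= rec[i]
    p_env <- max(prec[i:length(tp)])
    area <- area + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  area
}

# dense softmax association over ALL super tokens, masked to a support set
oracle_dense_association <- function(X, S, support) {
  N <- nrow(X); m <- nrow(S)
  L <- X %*% t(S) / sqrt(ncol(X))
  L[!support] <- -Inf
  Q <- matrix(0, N, m)
  for (i in 1:N) {
    z <- exp(L[i, ] - max(L[i, ]))
    Q[i, ] <- z / sum(z)
  }
  Q
}

# random valid pixel boxes
random_boxes <- function(n, size = 100) {
  x1 <- runif(n, 0, size - 10); y1 <- runif(n, 0, size - 10)
  cbind(x1, y1, x1 + runif(n, 2, size / 2), y1 + runif(n, 2, size / 2))
}

# convert a sparse association (N x 9 + neighbor index) to a dense N x m matrix
assoc_to_dense <- function(assoc) {
  Q <- matrix(0, nrow(assoc$Q), assoc$m)
  for (o in 1:9) {
    ok <- !is.na(assoc$idx[, o])
    Q[cbind(which(ok), assoc$idx[ok, o])] <- assoc$Q[ok, o]
  }
  Q
}

digest_file <- function(f) unname(tools::md5sum(f))
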