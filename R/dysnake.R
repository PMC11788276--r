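# Dynamic snake convolution: continuity-constrained deformable sampling.
#
# A snake kernel of length k extends from each output pixel along one axis
# (the "morph" axis: x = along width, y = along height). A 3x3 convolution +
# batch norm + tanh predicts a bounded offset field with 2k channels per
# pixel: k morph-axis step perturbations and k perpendicular drifts. Sampling
# coordinates are accumulated from the kernel center outward -- each position
# references the previous one, stepping 1 + offset along the morph axis and
# drifting by the perpendicular offset -- so consecutive samples never
# separate by more than two pixels (continuity constraint). With all offsets
# zero the snake degenerates to a straight axis-aligned k x 1 line and the
# branch equals a plain k x 1 convolution.

#' Compute the bounded snake offset field
#'
#' @param m A snake branch module (internal) or any module exposing
#'   `offset_conv` / `offset_bn` children.
#' @param x Input features, dim `c(H, W, C, N)`.
#' @param train Keep caches for the backward pass.
#' @return Array dim `c(H, W, 2k, N)` with entries strictly inside (-1, 1).
#' @export
snake_offsets <- function(m, x, train = FALSE) {
  z <- sg_forward(m$modules$offset_conv, x, train)
  z <- sg_forward(m$modules$offset_bn, z, train)
  tanh(z)
}

#' Snake sampling coordinates from an offset field
#'
#' Builds per-kernel-position sampling coordinates. The center position
#' (index `(k+1)/2`) coincides with the pixel's own coordinate; moving
#' outward, the morph-axis coordinate advances by `1 + step offset` and the
#' perpendicular coordinate accumulates the drift offsets, so the snake can
#' freely select its movement direction while every position references the
#' previous one.
#'
#' @param offsets Array `c(H, W, 2k, N)`; channels `1..k` are morph-axis step
#'   offsets, `k+1..2k` perpendicular drifts.
#' @param morph `"x"` (kernel along width) or `"y"` (kernel along height).
#' @param H,W Feature extents.
#' @return List with 0-based coordinate matrices `ys`, `xs` (each
#'   `(k*H*W) x N`, ordered to match the sampled stack layout), the raw
#'   unclamped coordinates, and bookkeeping for the backward pass.
#' @export
snake_coordinates <- function(offsets, morph = c("x", "y"), H, W) {
  morph <- match.arg(morph)
  d <- dim(offsets)
  k <- d[3] %/% 2L
  N <- d[4]
  mid <- (k + 1L) %/% 2L  # center index (k odd)
  # cumulative morph steps s_j and perpendicular drifts t_j, per pixel
  s <- array(0, dim = c(H, W, k, N))
  t <- array(0, dim = c(H, W, k, N))
  step_off <- offsets[, , seq_len(k), , drop = FALSE]
  drift_off <- offsets[, , k + seq_len(k), , drop = FALSE]
  if (mid < k) for (j in (mid + 1L):k) {
    s[, , j, ] <- s[, , j - 1L, , drop = FALSE] + 1 + step_off[, , j, , drop = FALSE]
    t[, , j, ] <- t[, , j - 1L, , drop = FALSE] + drift_off[, , j, , drop = FALSE]
  }
  if (mid > 1L) for (j in (mid - 1L):1L) {
    s[, , j, ] <- s[, , j + 1L, , drop = FALSE] - 1 - step_off[, , j, , drop = FALSE]
    t[, , j, ] <- t[, , j + 1L, , drop = FALSE] + drift_off[, , j, , drop = FALSE]
  }
  base_h <- array(rep(seq_len(H) - 1, times = W * k * N), dim = c(H, W, k, N))
  base_w <- array(rep(rep(seq_len(W) - 1, each = H), times = k * N),
                  dim = c(H, W, k, N))
  if (morph == "x") {
    xs_raw <- base_w + s
    ys_raw <- base_h + t
  } else {
    ys_raw <- base_h + s
    xs_raw <- base_w + t
  }
  xs <- pmin(pmax(xs_raw, 0), W - 1)
  ys <- pmin(pmax(ys_raw, 0), H - 1)
  # reorder (H, W, k, N) -> stack order
  perm <- if (morph == "x") c(3, 1, 2, 4) else c(1, 3, 2, 4)  # (k,H,W,N) / (H,k,W,N)
  M <- k * H * W
  list(
    ys = matrix(aperm(ys, perm), M, N), xs = matrix(aperm(xs, perm), M, N),
    mask_y = matrix(aperm(ys_raw > 0 & ys_raw < H - 1, perm), M, N),
    mask_x = matrix(aperm(xs_raw > 0 & xs_raw < W - 1, perm), M, N),
    k = k, mid = mid, morph = morph, H = H, W = W, N = N, perm = perm
  )
}

# scatter coordinate gradients back onto the offset field
snake_coordinates_backward <- function(co, gys, gxs) {
  k <- co$k; H <- co$H; W <- co$W; N <- co$N; mid <- co$mid
  gys <- gys * co$mask_y
  gxs <- gxs * co$mask_x
  inv <- order(co$perm)
  dims_perm <- c(H, W, k, N)[co$perm]
  gy4 <- aperm(array(gys, dim = dims_perm), inv)
  gx4 <- aperm(array(gxs, dim = dims_perm), inv)
  # gy4/gx4 now (H, W, k, N); map to morph-step grad gs and drift grad gt
  if (co$morph == "x") { gs4 <- gx4; gt4 <- gy4 } else { gs4 <- gy4; gt4 <- gx4 }
  goff <- array(0, dim = c(H, W, 2L * k, N))
  # positive arm: step/drift offsets at i influence all positions j >= i;
  # negative arm: positions j <= i (the step enters with a minus sign there)
  if (mid < k) {
    acc_s <- 0; acc_t <- 0
    for (i in k:(mid + 1L)) {
      acc_s <- acc_s + as.numeric(gs4[, , i, ])
      acc_t <- acc_t + as.numeric(gt4[, , i, ])
      goff[, , i, ] <- acc_s
      goff[, , k + i, ] <- acc_t
    }
  }
  if (mid > 1L) {
    acc_s <- 0; acc_t <- 0
    for (i in 1L:(mid - 1L)) {
      acc_s <- acc_s + as.numeric(gs4[, , i, ])
      acc_t <- acc_t + as.numeric(gt4[, , i, ])
      goff[, , i, ] <- -acc_s
      goff[, , k + i, ] <- acc_t
    }
  }
  goff
}

#' Bilinear sampling of a feature map along snake coordinates
#'
#' @param features Array `c(H, W, C, N)`.
#' @param coords Output of [snake_coordinates()].
#' @return The sampled stack: dim `c(k*H, W, C, N)` for morph x, or
#'   `c(H, k*W, C, N)` for morph y. Integer coordinates reproduce input
#'   values exactly.
#' @export
bilinear_sample <- function(features, coords) {
  d <- dim(features)
  out <- cpp_bilinear_gather(features, d[1], d[2], d[3], d[4], coords$ys, coords$xs)
  newd <- if (coords$morph == "x") c(coords$k * d[1], d[2], d[3], d[4])
          else c(d[1], coords$k * d[2], d[3], d[4])
  dim(out) <- newd
  out
}

# one snake branch: offset conv+bn -> tanh -> sample -> (k x 1) conv stride k
# -> group norm -> SiLU
build_snake_branch <- function(c_in, c_out, k, morph) {
  groups <- if (c_out %% 4 == 0) c_out %/% 4 else 1L
  m <- sg_module("snake_branch", c_in = c_in, c_out = c_out, k = k, morph = morph)
  m$modules$offset_conv <- layer_conv2d(c_in, 2L * k, 3, 1, bias = FALSE)
  m$modules$offset_bn <- layer_batchnorm(2L * k)
  kk <- if (morph == "x") c(k, 1L) else c(1L, k)
  m$modules$dsc <- layer_conv2d(c_in, c_out, kk, kk, bias = FALSE, pad = c(0L, 0L))
  m$modules$gn <- layer_groupnorm(c_out, groups)
  m$modules$act <- layer_silu()
  m
}

#' @export
sg_forward.sg_snake_branch <- function(m, x, train = FALSE) {
  z <- sg_forward(m$modules$offset_conv, x, train)
  z <- sg_forward(m$modules$offset_bn, z, train)
  off <- tanh(z)
  d <- dim(x)
  co <- snake_coordinates(off, m$morph, d[1], d[2])
  stack <- cpp_bilinear_gather(x, d[1], d[2], d[3], d[4], co$ys, co$xs)
  newd <- if (m$morph == "x") c(m$k * d[1], d[2], d[3], d[4])
          else c(d[1], m$k * d[2], d[3], d[4])
  dim(stack) <- newd
  h <- sg_forward(m$modules$dsc, stack, train)
  h <- sg_forward(m$modules$gn, h, train)
  y <- sg_forward(m$modules$act, h, train)
  if (train) m$cache <- list(x = x, off = off, co = co, din = d)
  y
}

#' @export
sg_backward.sg_snake_branch <- function(m, gy) {
  cc <- m$cache; d <- cc$din
  g <- sg_backward(m$modules$act, gy)
  g <- sg_backward(m$modules$gn, g)
  gstack <- sg_backward(m$modules$dsc, g)
  M <- m$k * d[1] * d[2]
  dim(gstack) <- c(M, d[3], d[4])
  bw <- cpp_bilinear_gather_backward(cc$x, d[1], d[2], d[3], d[4],
                                     cc$co$ys, cc$co$xs, gstack)
  goff <- snake_coordinates_backward(cc$co, bw$gys, bw$gxs)
  gz <- goff * (1 - cc$off^2)
  gz <- sg_backward(m$modules$offset_bn, gz)
  gx_off <- sg_backward(m$modules$offset_conv, gz)
  bw$gx + gx_off
}

#' Dynamic snake convolution block
#'
#' Three parallel branches -- a standard k x k conv block, a morph-x snake
#' branch and a morph-y snake branch -- concatenated to `3 c_out` channels
#' and fused back to `c_out` by a 1x1 conv block. Shape-preserving.
#'
#' @param c_in,c_out Channels.
#' @param k Snake kernel length (odd).
#' @return A block module.
#' @export
build_dysnakeconv <- function(c_in, c_out, k = 3L) {
  stopifnot_pos_int(c_in = c_in, c_out = c_out, k = k)
  if (k %% 2 == 0) stop("invalid config: snake kernel length must be odd")
  m <- sg_module("dysnakeconv", c_in = c_in, c_out = c_out, k = k)
  m$modules$std <- build_conv_block(c_in, c_out, k, 1)
  m$modules$snake_x <- build_snake_branch(c_in, c_out, k, "x")
  m$modules$snake_y <- build_snake_branch(c_in, c_out, k, "y")
  m$modules$fuse <- build_conv_block(3L * c_out, c_out, 1, 1)
  m
}

#' @export
sg_forward.sg_dysnakeconv <- function(m, x, train = FALSE) {
  a <- sg_forward(m$modules$std, x, train)
  b <- sg_forward(m$modules$snake_x, x, train)
  cc <- sg_forward(m$modules$snake_y, x, train)
  sg_forward(m$modules$fuse, cat_channels(list(a, b, cc)), train)
}

#' @export
sg_backward.sg_dysnakeconv <- function(m, gy) {
  g <- sg_backward(m$modules$fuse, gy)
  gs <- split_channels(g, rep(m$c_out, 3))
  sg_backward(m$modules$std, gs[[1]]) +
    sg_backward(m$modules$snake_x, gs[[2]]) +
    sg_backward(m$modules$snake_y, gs[[3]])
}

#' C2f block with snake-convolution bottlenecks
#'
#' The C2f layout of [build_c2f()] with each bottleneck's second 3x3 conv
#' block replaced by a [build_dysnakeconv()] unit at the hidden width.
#' Accepts any input spatial size (the snake sampling adapts to the feature
#' map extents).
#'
#' @param c_in,c_out Channels; `c_out` must be even.
#' @param n Number of bottlenecks.
#' @param shortcut Residual add inside each bottleneck.
#' @param k Snake kernel length.
#' @return A block module.
#' @export
build_c2f_dysnake <- function(c_in, c_out, n = 1L, shortcut = TRUE, k = 3L) {
  build_c2f(c_in, c_out, n, shortcut,
            bottleneck_factory = function(c, sc)
              build_bottleneck(c, sc, second = build_dysnakeconv(c, c, k)))
}
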