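# Dynamic snake convolution: offset bounds, coordinate construction,
# bilinear sampling, zero-offset equivalence, continuity, translation.

zero_offsets <- function(m) {
  # zero the offset convolution so the snake degenerates to a straight line
  for (br in c("snake_x", "snake_y")) {
    if (is.null(m$modules[[br]])) next
    m$modules[[br]]$modules$offset_conv$params$weight$value[] <- 0
    m$modules[[br]]$modules$offset_bn$params$gamma$value[] <- 1
    m$modules[[br]]$modules$offset_bn$params$beta$value[] <- 0
  }
  m
}

test_that("offsets are tanh-bounded and zero-initialized offsets give a straight line", {
  set.seed(4)
  br <- serpensgate:::build_snake_branch(3, 4, 3, "x")
  x <- array(rnorm(8 * 8 * 3) * 5, dim = c(8, 8, 3, 1))
  off <- serpensgate:::snake_offsets(br, x)
  expect_true(all(off > -1 & off < 1))
  expect_equal(dim(off), c(8, 8, 6, 1))
  co <- snake_coordinates(array(0, dim = c(8, 8, 6, 1)), "x", 8, 8)
  # zero offsets, morph x: relative coordinates {(0,-1),(0,0),(0,+1)}
  xs <- array(co$xs, dim = c(3, 8, 8))
  ys <- array(co$ys, dim = c(3, 8, 8))
  expect_equal(xs[, 3, 5] - (5 - 1), c(-1, 0, 1))
  expect_equal(ys[, 3, 5], rep(3 - 1, 3))
  coy <- snake_coordinates(array(0, dim = c(8, 8, 6, 1)), "y", 8, 8)
  ysy <- array(coy$ys, dim = c(8, 3, 8))
  xsy <- array(coy$xs, dim = c(8, 3, 8))
  expect_equal(ysy[4, , 6] - (4 - 1), c(-1, 0, 1))
  expect_equal(xsy[4, , 6], rep(6 - 1, 3))
})

test_that("constant +0.5 morph steps displace outer samples by 1.5; drifts accumulate", {
  off <- array(0, dim = c(8, 8, 6, 1))
  off[, , 1:3, ] <- 0.5                 # morph-axis step offsets
  co <- snake_coordinates(off, "x", 8, 8)
  xs <- array(co$xs, dim = c(3, 8, 8))
  expect_equal(xs[, 4, 4] - 3, c(-1.5, 0, 1.5))
  # positive-arm drifts (0.2, 0.4) accumulate to (0.2, 0.6) with k = 5
  off5 <- array(0, dim = c(6, 6, 10, 1))
  off5[, , 5 + 4, ] <- 0.2              # drift at arm position 4 (mid = 3)
  off5[, , 5 + 5, ] <- 0.4
  co5 <- snake_coordinates(off5, "x", 6, 6)
  ys <- array(co5$ys, dim = c(5, 6, 6))
  expect_equal(ys[4, 3, 3] - 2, 0.2)
  expect_equal(ys[5, 3, 3] - 2, 0.6)
})

test_that("continuity: consecutive morph-axis samples differ from a unit step by < 1", {
  set.seed(8)
  for (trial in 1:10) {
    off <- array(tanh(rnorm(8 * 8 * 6)), dim = c(8, 8, 6, 1))
    co <- snake_coordinates(off, "x", 8, 8)
    xs_raw <- array(co$xs, dim = c(3, 8, 8))
    # use interior pixels so clamping does not bite
    d1 <- xs_raw[2, 4, 4] - xs_raw[1, 4, 4]
    d2 <- xs_raw[3, 4, 4] - xs_raw[2, 4, 4]
    expect_lt(abs(d1 - 1), 1)
    expect_lt(abs(d2 - 1), 1)
  }
})

test_that("bilinear sampler: exact at integers, midpoint averaging, matches loop oracle", {
  set.seed(15)
  feat <- matrix(rnorm(16), 4, 4)
  x4 <- array(feat, dim = c(4, 4, 1, 1))
  # integer coordinates reproduce the input
  ys <- matrix(c(0, 1, 2, 3), ncol = 1)
  xs <- matrix(c(0, 2, 1, 3), ncol = 1)
  got <- serpensgate:::cpp_bilinear_gather(x4, 4L, 4L, 1L, 1L, ys, xs)
  expect_equal(as.numeric(got), feat[cbind(ys + 1, xs + 1)])
  # midpoint between 0 and 1 gives 0.5
  f2 <- array(c(0, 1, 0, 1), dim = c(2, 2, 1, 1))
  mid <- serpensgate:::cpp_bilinear_gather(f2, 2L, 2L, 1L, 1L,
                                           matrix(0.5), matrix(0))
  expect_equal(as.numeric(mid), 0.5)
  # random coordinates vs the scalar loop oracle
  for (trial in 1:20) {
    yy <- runif(1, 0, 3); xx <- runif(1, 0, 3)
    got <- serpensgate:::cpp_bilinear_gather(x4, 4L, 4L, 1L, 1L,
                                             matrix(yy), matrix(xx))
    expect_equal(as.numeric(got), oracle_bilinear(feat, yy, xx), tolerance = 1e-12)
  }
})

test_that("zero-offset snake branches equal plain axis-aligned convolutions", {
  set.seed(23)
  # oracle: 1-D convolution along one axis with replicate (clamped) padding,
  # matching the coordinate clamping of the sampler
  # sample index j of the (k x 1) / (1 x k) snake kernel reaches the pixel
  # offset j - (k+1)/2 along the morph axis, clamped at the borders
  oracle_axis_conv <- function(x3, w, morph, k = 3) {
    H <- dim(x3)[1]; W <- dim(x3)[2]; Cin <- dim(x3)[3]; Cout <- dim(w)[4]
    out <- array(0, dim = c(H, W, Cout))
    for (co in 1:Cout) for (h in 1:H) for (wdx in 1:W) {
      acc <- 0
      for (ci in 1:Cin) for (j in 1:k) {
        if (morph == "x") {
          wi <- min(max(wdx + j - (k + 1) / 2, 1), W)
          acc <- acc + x3[h, wi, ci] * w[j, 1, ci, co]
        } else {
          hi <- min(max(h + j - (k + 1) / 2, 1), H)
          acc <- acc + x3[hi, wdx, ci] * w[1, j, ci, co]
        }
      }
      out[h, wdx, co] <- acc
    }
    out
  }
  for (morph in c("x", "y")) {
    br <- serpensgate:::build_snake_branch(3, 4, 3, morph)
    br$modules$offset_conv$params$weight$value[] <- 0
    br$modules$offset_bn$params$beta$value[] <- 0
    x <- array(rnorm(10 * 12 * 3), dim = c(10, 12, 3, 1))
    got <- sg_forward(br, x)
    w <- br$modules$dsc$params$weight$value   # (k,1) for morph x, (1,k) for y
    ref_conv <- array(oracle_axis_conv(x[, , , 1], w, morph),
                      dim = c(10, 12, 4, 1))
    ref <- sg_forward(br$modules$gn, ref_conv)
    ref <- sg_forward(br$modules$act, ref)
    expect_equal(got, ref, tolerance = 1e-5)
  }
})

test_that("zero-offset sampling is translation-consistent under whole-pixel shifts", {
  set.seed(31)
  x <- array(rnorm(12 * 12 * 2), dim = c(12, 12, 2, 1))
  off <- array(0, dim = c(12, 12, 6, 1))
  co <- snake_coordinates(off, "x", 12, 12)
  s1 <- bilinear_sample(x, co)
  xs <- x[, c(2:12, 1), , , drop = FALSE]     # shift left by one column
  s2 <- bilinear_sample(xs, co)
  # interior columns shift identically (matching crop away from the border)
  expect_equal(s2[7:30, 2:9, , , drop = FALSE],
               s1[7:30, 3:10, , , drop = FALSE], tolerance = 1e-12)
})

test_that("DySnakeConv block and C2f variant are shape-preserving on odd sizes", {
  set.seed(6)
  b <- build_dysnakeconv(8, 8, 3)
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8, 1))
  expect_equal(dim(sg_forward(b, x)), c(16, 16, 8, 1))
  expect_error(build_dysnakeconv(8, 8, 4), "odd")
  cb <- build_c2f_dysnake(8, 8, 1, TRUE)
  x2 <- array(rnorm(13 * 17 * 8), dim = c(13, 17, 8, 1))
  expect_equal(dim(sg_forward(cb, x2)), c(13, 17, 8, 1))
  expect_error(build_c2f_dysnake(8, 7), "even")
})

test_that("DySnakeConv parameter count equals the five-component hand-sum", {
  k <- 3; c_in <- 8; c_out <- 8
  conv_p <- function(ci, co, kk) ci * co * kk + 2 * co
  branch <- (c_in * (2 * k) * 9 + 2 * (2 * k)) +  # offset conv + its BN
    (c_in * c_out * k) +                          # k x 1 snake conv
    2 * c_out                                     # group norm affine
  expected <- conv_p(c_in, c_out, 9) + 2 * branch + conv_p(3 * c_out, c_out, 1)
  expect_equal(sum(count_params(build_dysnakeconv(c_in, c_out, k))), expected)
})
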