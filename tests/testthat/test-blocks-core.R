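# Building blocks: parameter accounting, shape laws, error handling.

count_total <- function(b) sum(count_params(b))

test_that("conv block parameter counts follow c_in*c_out*k^2 + 2*c_out", {
  cases <- list(
    list(args = c(3, 16, 3, 2), expect = 464),
    list(args = c(1, 1, 1, 1), expect = 3),
    list(args = c(16, 32, 3, 2), expect = 4672),
    list(args = c(128, 256, 3, 2), expect = 295424)
  )
  for (cs in cases) {
    b <- do.call(build_conv_block, as.list(cs$args))
    expect_equal(count_total(b), cs$expect)
    expect_equal(count_params(b)[["fixed"]], 0)
  }
  # counts are pure functions of config
  expect_equal(count_params(build_conv_block(16, 32, 3, 2)),
               count_params(build_conv_block(16, 32, 3, 2)))
})

test_that("conv block rejects non-positive configuration", {
  expect_error(build_conv_block(0, 16, 3, 2), "invalid config")
  expect_error(build_conv_block(3, 16, -1, 2), "invalid config")
})

test_that("stock C2f reproduces the printed neck counts", {
  expect_equal(count_total(build_c2f(384, 128, 1, FALSE)), 148224)
  expect_equal(count_total(build_c2f(192, 64, 1, FALSE)), 37248)
  expect_equal(count_total(build_c2f(448, 128, 1, FALSE)), 156416)
  expect_equal(count_total(build_c2f(384, 256, 1, FALSE)), 493056)
  expect_error(build_c2f(16, 15, 1), "even")
})

test_that("C2f count equals the conv-block component sum", {
  # independent hand-sum over the layout: cv1, n bottlenecks, cv2
  c_in <- 48; c_out <- 32; n <- 2
  cc <- c_out / 2
  conv_p <- function(ci, co, k) ci * co * k^2 + 2 * co
  expected <- conv_p(c_in, 2 * cc, 1) +
    n * (conv_p(cc, cc, 3) + conv_p(cc, cc, 3)) +
    conv_p((2 + n) * cc, c_out, 1)
  expect_equal(count_total(build_c2f(c_in, c_out, n, TRUE)), expected)
})

test_that("SPPELAN counts and shape preservation", {
  expect_equal(count_total(build_sppelan(256, 256, 1024)), 1313280)
  expect_equal(count_total(build_sppelan(8, 8, 16)), 688)  # cv1 160 + cv5 528
  set.seed(3)
  b <- build_sppelan(8, 8, 16)
  x <- array(rnorm(20 * 20 * 8), dim = c(20, 20, 8, 1))
  expect_equal(dim(sg_forward(b, x)), c(20, 20, 8, 1))
  expect_error(build_sppelan(0, 8, 16), "invalid config")
})

test_that("detect head matches the printed total and the component hand-sum", {
  d <- count_params(build_detect_head(30, c(64, 128, 256), 16))
  expect_equal(d[["trainable"]], 757146)
  expect_equal(d[["fixed"]], 16)
  # independent per-branch hand-sum for a single-scale head
  nc <- 1; ch <- 64; reg_max <- 16
  c2 <- max(16, ch %/% 4, 4 * reg_max)
  c3 <- max(ch, min(nc, 100))
  conv_p <- function(ci, co, k) ci * co * k^2 + 2 * co
  expected <- conv_p(ch, c2, 3) + conv_p(c2, c2, 3) + (c2 * 4 * reg_max + 4 * reg_max) +
    conv_p(ch, c3, 3) + conv_p(c3, c3, 3) + (c3 * nc + nc) + reg_max
  expect_equal(sum(count_params(build_detect_head(1, 64, 16))), expected)
  expect_error(build_detect_head(3, integer(0)), "invalid config|>= 1 scale")
})

test_that("DFL projection maps a one-hot bin distribution to its offset", {
  reg_max <- 16
  for (j in c(0, 3, 15)) {
    logits <- matrix(-30, reg_max, 1)
    logits[j + 1, 1] <- 30
    expect_equal(dfl_expectation(logits), j, tolerance = 1e-9)
  }
})

test_that("parameter-free nodes count zero", {
  expect_equal(count_params(serpensgate:::build_upsample()),
               c(trainable = 0, fixed = 0))
  expect_equal(count_params(serpensgate:::build_concat()),
               c(trainable = 0, fixed = 0))
})

test_that("stride law: five stride-2 convs bring 640 to 20 and a conv block halves odd-free sizes", {
  set.seed(5)
  sizes <- 640
  for (i in 1:5) sizes <- c(sizes, tail(sizes, 1) / 2)
  expect_equal(tail(sizes, 1), 20)
  b <- build_conv_block(2, 3, 3, 2)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2, 1))
  expect_equal(dim(sg_forward(b, x))[1:2], c(8, 8))
  b1 <- build_conv_block(2, 3, 3, 1)
  expect_equal(dim(sg_forward(b1, x))[1:2], c(16, 16))
})

test_that("conv block forward agrees with a direct looped convolution", {
  set.seed(11)
  b <- build_conv_block(3, 4, 3, 2)
  x <- array(rnorm(10 * 10 * 3), dim = c(10, 10, 3, 1))
  got <- sg_forward(b$modules$conv, x)
  ref <- oracle_conv2d(x[, , , 1], b$modules$conv$params$weight$value, stride = 2)
  expect_equal(got[, , , 1], ref, tolerance = 1e-12)
})
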