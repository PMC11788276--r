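# Super token attention: grid means, sparse association, update, attention
# forward, parameter and flop accounting.

test_that("initial super tokens are grid-cell means", {
  # 4x4 grid of distinct values, 2x2 cells: four hand-computed means
  v <- matrix(1:16, 4, 4, byrow = TRUE)      # row-major values
  X <- matrix(as.numeric(t(v)), ncol = 1)    # token order row-major
  tg <- token_grid(X, 4, 4)
  st <- init_super_tokens(tg, 2, 2)
  expect_equal(st$m, 4)
  expect_equal(as.numeric(st$S),
               c(mean(c(1, 2, 5, 6)), mean(c(3, 4, 7, 8)),
                 mean(c(9, 10, 13, 14)), mean(c(11, 12, 15, 16))))
  # whole-grid cell: single super token equals the global mean
  st1 <- init_super_tokens(tg, 4, 4)
  expect_equal(st1$m, 1)
  expect_equal(as.numeric(st1$S), mean(v))
  # constant map: every super token equals the constant
  tgc <- token_grid(matrix(3.5, 16, 2), 4, 4)
  stc <- init_super_tokens(tgc, 2, 2)
  expect_true(all(abs(stc$S - 3.5) < 1e-12))
  expect_error(init_super_tokens(tg, 5, 2), "invalid config")
})

test_that("association rows sum to 1; m = 1 gives the all-ones column", {
  set.seed(12)
  X <- matrix(rnorm(36 * 4), 36, 4)
  tg <- token_grid(X, 6, 6)
  st <- init_super_tokens(tg, 6, 6)
  q <- token_association(tg, st)
  expect_equal(as.numeric(q$Q[, 5]), rep(1, 36))   # own cell at offset 5
  expect_equal(rowSums(q$Q), rep(1, 36))
  # identical logits over a full 9-neighborhood: uniform 1/9
  tgc <- token_grid(matrix(0, 81, 3), 9, 9)
  stc <- init_super_tokens(tgc, 3, 3)
  qc <- token_association(tgc, stc)
  center_token <- (4 - 1) * 9 + 5               # row 4, col 5: interior
  expect_equal(as.numeric(qc$Q[center_token, ]), rep(1 / 9, 9))
})

test_that("sparse association equals the dense softmax oracle masked to the support", {
  set.seed(13)
  for (trial in 1:8) {
    H <- sample(4:8, 1); W <- sample(4:8, 1); C <- sample(2:5, 1)
    X <- matrix(rnorm(H * W * C), H * W, C)
    tg <- token_grid(X, H, W)
    st <- init_super_tokens(tg, 2, 2)
    q <- token_association(tg, st)
    dense <- assoc_to_dense(q)
    support <- matrix(FALSE, H * W, st$m)
    for (o in 1:9) {
      ok <- !is.na(q$idx[, o])
      support[cbind(which(ok), q$idx[ok, o])] <- TRUE
    }
    ref <- oracle_dense_association(X, st$S, support)
    expect_equal(dense, ref, tolerance = 1e-10)
  }
})

test_that("update is a convex combination: dense oracle, identity case, constant case", {
  set.seed(14)
  # random 6-token, 2-super-token instance vs the dense product
  X <- matrix(rnorm(6 * 3), 6, 3)
  tg <- token_grid(X, 2, 3)
  st <- init_super_tokens(tg, 2, 2)      # cells: 1x2 -> m = 2
  q <- token_association(tg, st)
  up <- update_super_tokens(q, tg, st)
  Qd <- assoc_to_dense(q)
  Qhat <- sweep(Qd, 2, colSums(Qd), "/")
  expect_equal(up$S, t(Qhat) %*% X, tolerance = 1e-12)
  # all tokens identical: every super token equals that token
  tgc <- token_grid(matrix(rep(c(1, 2, 3), each = 16), 16, 3), 4, 4)
  stc <- init_super_tokens(tgc, 2, 2)
  upc <- update_super_tokens(token_association(tgc, stc), tgc, stc)
  expect_equal(upc$S, matrix(rep(c(1, 2, 3), each = 4), 4, 3), tolerance = 1e-12)
  # Q = identity (N = m): S = X exactly
  idq <- structure(list(Q = cbind(rep(1, 4), matrix(0, 4, 8)),
                        idx = cbind(1:4, matrix(NA_integer_, 4, 8)),
                        colsum = rep(1, 4), m = 4, d = 3),
                   class = "association_map")
  tg4 <- token_grid(matrix(rnorm(12), 4, 3), 2, 2)
  prev <- init_super_tokens(tg4, 1, 1)
  expect_equal(update_super_tokens(idq, tg4, prev)$S, tg4$X)
})

test_that("super tokens stay in the coordinate-wise convex hull across iterations", {
  set.seed(16)
  for (trial in 1:10) {
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    X <- matrix(rnorm(H * W * 3), H * W, 3)
    tg <- token_grid(X, H, W)
    st <- init_super_tokens(tg, 2, 2)
    for (it in 1:3) {
      q <- token_association(tg, st)
      expect_equal(rowSums(q$Q), rep(1, H * W), tolerance = 1e-6)
      st <- update_super_tokens(q, tg, st)
      for (j in 1:ncol(X)) {
        expect_true(all(st$S[, j] >= min(X[, j]) - 1e-9))
        expect_true(all(st$S[, j] <= max(X[, j]) + 1e-9))
      }
    }
  }
})

test_that("attention block is shape-preserving and batch-consistent", {
  set.seed(17)
  m <- build_stoken_attention(8, heads = 2, grid = c(2, 2))
  for (hw in list(c(6, 6), c(7, 5))) {
    x <- array(rnorm(hw[1] * hw[2] * 8 * 2), dim = c(hw[1], hw[2], 8, 2))
    y <- sg_forward(m, x)
    expect_equal(dim(y), dim(x))
  }
  expect_error(build_stoken_attention(10, heads = 4), "divisible")
})

test_that("parameter count formula and its fixed part", {
  expect_equal(sum(sta_param_count(256)), 262562)
  expect_equal(sta_param_count(256)[["trainable"]], 262400)
  expect_equal(sta_param_count(1), c(trainable = 5, fixed = 162))
  for (d in c(2, 16, 64)) expect_equal(sta_param_count(d)[["fixed"]], 162)
  # the built block carries exactly the counted parameters
  b <- build_stoken_attention(16, heads = 4)
  expect_equal(count_params(b),
               c(trainable = sta_param_count(16)[["trainable"]], fixed = 162))
})

test_that("sampling flop count is 19NC with the stated decomposition", {
  expect_equal(sts_complexity(1, 1)[["total"]], 19)
  expect_equal(sts_complexity(400, 256)[["total"]], 1945600)
  set.seed(18)
  for (trial in 1:10) {
    N <- sample(1:1000, 1); C <- sample(1:512, 1)
    cx <- sts_complexity(N, C)
    expect_equal(cx[["init"]], N * C)
    expect_equal(cx[["assoc"]], 9 * N * C)
    expect_equal(cx[["update"]], 9 * N * C)
    expect_equal(cx[["init"]] + cx[["assoc"]] + cx[["update"]], cx[["total"]])
  }
})
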