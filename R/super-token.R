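# Super Token Attention: soft k-means token clustering in token space.
#
# A C x H x W feature map is flattened to N = H*W visual tokens X (N x C,
# row-major). Initial super tokens are grid-cell means; one or more sampling
# iterations then alternate (i) a sparse, attention-style association
# Q = softmax(X S^T / sqrt(C)) restricted to each token's 3x3 super-token
# neighborhood and (ii) the update S = Qhat^T X with Qhat the
# column-normalized Q. Multi-head self-attention runs over the m << N super
# tokens, the result is mapped back to tokens through Q, projected, and added
# residually. One sampling pass costs 19*N*C flops: N*C for the grid means
# and 9*N*C each for the sparse association and the update.

#' Token grid from a matrix or feature map
#'
#' @param X An `N x C` token matrix (rows are tokens, row-major over the
#'   spatial grid: token `t` sits at row `(t-1) %/% W + 1`, column
#'   `(t-1) %% W + 1`).
#' @param H,W Spatial extents with `N = H * W`.
#' @return A `token_grid` list.
#' @export
token_grid <- function(X, H, W) {
  X <- as.matrix(X)
  if (nrow(X) != H * W) stop("token_grid: nrow(X) must equal H * W")
  structure(list(X = X, H = H, W = W, N = H * W, C = ncol(X)),
            class = "token_grid")
}

# token row/col (1-based) for every token index
.token_rc <- function(H, W) {
  t <- seq_len(H * W)
  list(r = (t - 1L) %/% W + 1L, c = (t - 1L) %% W + 1L)
}

#' Initialize super tokens as grid-cell means
#'
#' Cells are `h x w`; when the extent is not divisible the edge cells are
#' ceil-sized (they absorb the remainder).
#'
#' @param tokens A [token_grid()].
#' @param h,w Grid cell sizes.
#' @return A `super_token_set`: `S` (`m x C` matrix of cell means), grid
#'   geometry, and the token-to-cell map.
#' @export
init_super_tokens <- function(tokens, h, w) {
  stopifnot(inherits(tokens, "token_grid"))
  if (h > tokens$H || w > tokens$W)
    stop("invalid config: grid cell larger than the token grid")
  gh <- ceiling(tokens$H / h)
  gw <- ceiling(tokens$W / w)
  rc <- .token_rc(tokens$H, tokens$W)
  cell_r <- pmin((rc$r - 1L) %/% h + 1L, gh)
  cell_c <- pmin((rc$c - 1L) %/% w + 1L, gw)
  cell <- (cell_r - 1L) * gw + cell_c          # row-major cell index
  cnt <- tabulate(cell, nbins = gh * gw)
  S <- rowsum(tokens$X, cell, reorder = TRUE) / cnt
  structure(list(S = S, grid_h = h, grid_w = w, gh = gh, gw = gw,
                 m = gh * gw, cell = cell, cell_r = cell_r, cell_c = cell_c,
                 count = cnt),
            class = "super_token_set")
}

# neighbor super-token indices for every token: <= 9 cells around its own
.neighbor_index <- function(supers) {
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- matrix(NA_integer_, length(supers$cell), 9)
  for (o in seq_len(9)) {
    rr <- supers$cell_r + offs$dr[o]
    cc <- supers$cell_c + offs$dc[o]
    ok <- rr >= 1 & rr <= supers$gh & cc >= 1 & cc <= supers$gw
    idx[ok, o] <- (rr[ok] - 1L) * supers$gw + cc[ok]
  }
  idx
}

#' Sparse token-to-super-token association
#'
#' For each token, attention-style logits `X_i . S_j / sqrt(C)` over the at
#' most 9 super tokens of its 3x3 grid neighborhood (fewer at borders),
#' softmax-normalized so every row of Q sums to 1.
#'
#' @param tokens A [token_grid()].
#' @param supers A super-token set from [init_super_tokens()] (or a previous
#'   [update_super_tokens()]).
#' @return An `association_map`: `Q` (`N x 9`, zero where the neighborhood
#'   falls off the grid), the neighbor index matrix, and the column sums.
#' @export
token_association <- function(tokens, supers) {
  idx <- .neighbor_index(supers)
  N <- tokens$N
  logits <- matrix(-Inf, N, 9)
  sc <- 1 / sqrt(tokens$C)
  for (o in seq_len(9)) {
    ok <- !is.na(idx[, o])
    if (any(ok))
      logits[ok, o] <- rowSums(tokens$X[ok, , drop = FALSE] *
                                 supers$S[idx[ok, o], , drop = FALSE]) * sc
  }
  mx <- apply(logits, 1, max)
  Z <- exp(logits - mx)
  Z[is.na(idx)] <- 0
  Q <- Z / rowSums(Z)
  cs <- numeric(supers$m)
  for (o in seq_len(9)) {
    ok <- !is.na(idx[, o])
    if (any(ok)) {
      add <- rowsum(Q[ok, o], idx[ok, o])
      cs[as.integer(rownames(add))] <- cs[as.integer(rownames(add))] + add
    }
  }
  structure(list(Q = Q, idx = idx, colsum = cs, m = supers$m, d = tokens$C),
            class = "association_map")
}

#' Update super tokens as Qhat-weighted token means
#'
#' `S = Qhat^T X` with `Qhat` the column-normalized association, so each
#' updated super token is a convex combination of tokens. A super token whose
#' association column is all zero keeps its previous value and is flagged.
#'
#' @param assoc An [token_association()] result.
#' @param tokens The [token_grid()].
#' @param prev The previous super-token set (geometry carrier).
#' @return The updated `super_token_set` with a `stale` attribute marking
#'   kept-over super tokens.
#' @export
update_super_tokens <- function(assoc, tokens, prev) {
  cs <- assoc$colsum
  S <- matrix(0, assoc$m, tokens$C)
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    if (any(ok)) {
      contrib <- rowsum(assoc$Q[ok, o] * tokens$X[ok, , drop = FALSE],
                        assoc$idx[ok, o])
      j <- as.integer(rownames(contrib))
      S[j, ] <- S[j, ] + contrib
    }
  }
  stale <- cs <= 0
  S[!stale, ] <- S[!stale, , drop = FALSE] / cs[!stale]
  if (any(stale)) S[stale, ] <- prev$S[stale, , drop = FALSE]
  out <- prev
  out$S <- S
  attr(out, "stale") <- which(stale)
  out
}

#' Sampling cost of the super-token association
#'
#' One sampling pass costs `19 N C` flops, decomposed as `N C` for the grid
#' initialization and `9 N C` each for the sparse association and the update.
#'
#' @param N Token count.
#' @param C Channel count.
#' @return Named vector with the three components and the `total`.
#' @export
sts_complexity <- function(N, C) {
  stopifnot_pos_int(N = N, C = C)
  c(init = N * C, assoc = 9 * N * C, update = 9 * N * C, total = 19 * N * C)
}

#' Parameter count of the super-token attention layer
#'
#' `3 dim^2` for the bias-free 1x1 qkv projection plus `dim^2 + dim` for the
#' biased 1x1 output projection, and 162 frozen values: two 3x3 unfold/fold
#' scatter-gather kernels of 81 entries each that realize the sparse 3x3
#' association as convolution-style unfold and fold.
#'
#' @param dim Channel count.
#' @return Named vector `c(trainable, fixed)`.
#' @export
sta_param_count <- function(dim) {
  stopifnot_pos_int(dim = dim)
  c(trainable = 3 * dim^2 + dim^2 + dim, fixed = 162)
}

# one-hot 3x3 unfold kernel: 9 output taps, each picking one neighbor
.unfold_kernel <- function() {
  k <- array(0, dim = c(3, 3, 1, 9))
  for (o in 1:9) k[((o - 1) %% 3) + 1, ((o - 1) %/% 3) + 1, 1, o] <- 1
  k
}

#' Super token attention block
#'
#' @param dim Channels (divisible by `heads`).
#' @param heads Attention heads over the super tokens.
#' @param grid Super-token grid cell size `c(h, w)`.
#' @param n_iter Sampling iterations (association + update).
#' @return A block module; forward is shape-preserving with a residual
#'   connection around the whole block.
#' @export
build_stoken_attention <- function(dim, heads = 4L, grid = c(5L, 5L), n_iter = 1L) {
  stopifnot_pos_int(dim = dim, heads = heads, n_iter = n_iter)
  if (dim %% heads != 0) stop("invalid config: dim must be divisible by heads")
  m <- sg_module("stoken_attention", dim = dim, heads = heads,
                 grid = grid, n_iter = n_iter)
  sd <- sqrt(2 / dim)
  m$params$w_qkv <- sg_param(matrix(rnorm(dim * 3 * dim, sd = sd), dim, 3 * dim))
  m$params$w_proj <- sg_param(matrix(rnorm(dim * dim, sd = sd), dim, dim))
  m$params$b_proj <- sg_param(numeric(dim))
  m$fixed$unfold_kernel <- .unfold_kernel()
  m$fixed$fold_kernel <- .unfold_kernel()
  m
}

.map_to_tokens <- function(x, n) {
  d <- dim(x)
  matrix(aperm(x[, , , n, drop = FALSE], c(2, 1, 3, 4)), d[1] * d[2], d[3])
}

.tokens_to_map <- function(X, H, W, C) {
  aperm(array(X, dim = c(W, H, C, 1)), c(2, 1, 3, 4))
}

.softmax_rows <- function(L) {
  Z <- exp(L - apply(L, 1, max))
  Z / rowSums(Z)
}

# MHSA over super tokens; returns output and caches for backward
.mhsa_forward <- function(S, w_qkv, heads) {
  C <- ncol(S)
  hd <- C %/% heads
  QKV <- S %*% w_qkv
  q <- QKV[, seq_len(C), drop = FALSE]
  k <- QKV[, C + seq_len(C), drop = FALSE]
  v <- QKV[, 2 * C + seq_len(C), drop = FALSE]
  out <- matrix(0, nrow(S), C)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    ix <- (h - 1) * hd + seq_len(hd)
    A[[h]] <- .softmax_rows(q[, ix, drop = FALSE] %*% t(k[, ix, drop = FALSE]) / sqrt(hd))
    out[, ix] <- A[[h]] %*% v[, ix, drop = FALSE]
  }
  list(out = out, A = A, q = q, k = k, v = v, hd = hd)
}

.mhsa_backward <- function(cc, S, w_qkv, heads, dout) {
  C <- ncol(S)
  hd <- cc$hd
  dq <- matrix(0, nrow(S), C); dk <- dq; dv <- dq
  for (h in seq_len(heads)) {
    ix <- (h - 1) * hd + seq_len(hd)
    A <- cc$A[[h]]
    dv[, ix] <- t(A) %*% dout[, ix, drop = FALSE]
    dA <- dout[, ix, drop = FALSE] %*% t(cc$v[, ix, drop = FALSE])
    dL <- A * (dA - rowSums(A * dA))
    dq[, ix] <- dL %*% cc$k[, ix, drop = FALSE] / sqrt(hd)
    dk[, ix] <- t(dL) %*% cc$q[, ix, drop = FALSE] / sqrt(hd)
  }
  dQKV <- cbind(dq, dk, dv)
  list(dS = dQKV %*% t(w_qkv), dW = t(S) %*% dQKV)
}

#' @export
sg_forward.sg_stoken_attention <- function(m, x, train = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (C != m$dim) stop(sprintf("stoken_attention: expected %d channels", m$dim))
  gh <- min(m$grid[1], H)
  gw <- min(m$grid[2], W)
  out <- x
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    X <- .map_to_tokens(x, n)
    tg <- token_grid(X, H, W)
    supers <- init_super_tokens(tg, gh, gw)
    s0 <- supers
    iters <- vector("list", m$n_iter)
    for (it in seq_len(m$n_iter)) {
      assoc <- token_association(tg, supers)
      prev <- supers
      supers <- update_super_tokens(assoc, tg, prev)
      iters[[it]] <- list(assoc = assoc, prevS = prev$S, S = supers$S)
    }
    att <- .mhsa_forward(supers$S, m$params$w_qkv$value, m$heads)
    lastQ <- iters[[m$n_iter]]$assoc
    Xup <- .assoc_matvec(lastQ, att$out)        # N x C: Q %*% S_att
    Y <- Xup %*% m$params$w_proj$value
    Y <- sweep(Y, 2, m$params$b_proj$value, "+")
    out[, , , n] <- .tokens_to_map(Y, H, W, C) + x[, , , n, drop = FALSE]
    if (train)
      caches[[n]] <- list(X = X, s0 = s0, iters = iters, att = att, Xup = Xup)
  }
  if (train) m$cache <- list(caches = caches, d = d, gh = gh, gw = gw)
  out
}

# Q %*% M over the sparse support (Q stored N x 9 with neighbor indices)
.assoc_matvec <- function(assoc, M) {
  out <- matrix(0, nrow(assoc$Q), ncol(M))
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    if (any(ok))
      out[ok, ] <- out[ok, , drop = FALSE] +
        assoc$Q[ok, o] * M[assoc$idx[ok, o], , drop = FALSE]
  }
  out
}

# t(Q) %*% M over the sparse support
.assoc_tmatvec <- function(assoc, M) {
  out <- matrix(0, assoc$m, ncol(M))
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    if (any(ok)) {
      contrib <- rowsum(assoc$Q[ok, o] * M[ok, , drop = FALSE], assoc$idx[ok, o])
      j <- as.integer(rownames(contrib))
      out[j, ] <- out[j, , drop = FALSE] + contrib
    }
  }
  out
}

#' @export
sg_backward.sg_stoken_attention <- function(m, gy) {
  cc <- m$cache
  d <- cc$d
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gx <- gy                                   # residual path
  for (n in seq_len(N)) {
    ca <- cc$caches[[n]]
    dY <- matrix(aperm(gy[, , , n, drop = FALSE], c(2, 1, 3, 4)), H * W, C)
    acc_grad(m$params$b_proj, colSums(dY))
    acc_grad(m$params$w_proj, t(ca$Xup) %*% dY)
    dXup <- dY %*% t(m$params$w_proj$value)
    last <- ca$iters[[m$n_iter]]
    # Xup = Q S_att : gradient to Q and to the attended super tokens
    dSatt <- .assoc_tmatvec(last$assoc, dXup)
    dQ_up <- .assoc_q_grad(last$assoc, dXup, ca$att$out)
    mb <- .mhsa_backward(ca$att, last$S, m$params$w_qkv$value, m$heads, dSatt)
    acc_grad(m$params$w_qkv, mb$dW)
    dS <- mb$dS
    dX <- matrix(0, H * W, C)
    for (it in rev(seq_len(m$n_iter))) {
      st <- ca$iters[[it]]
      bk <- .sts_iteration_backward(st, ca$X, dS,
                                    if (it == m$n_iter) dQ_up else NULL)
      dX <- dX + bk$dX
      dS <- bk$dS_prev
    }
    # initial super tokens are grid-cell means of the tokens
    dX <- dX + dS[ca$s0$cell, , drop = FALSE] / ca$s0$count[ca$s0$cell]
    gx[, , , n] <- gx[, , , n, drop = FALSE] + .tokens_to_map(dX, H, W, C)
  }
  gx
}

# gradient of sum(dXup * (Q %*% M)) w.r.t. the sparse entries of Q
.assoc_q_grad <- function(assoc, dXup, M) {
  g <- matrix(0, nrow(assoc$Q), 9)
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    if (any(ok))
      g[ok, o] <- rowSums(dXup[ok, , drop = FALSE] *
                            M[assoc$idx[ok, o], , drop = FALSE])
  }
  g
}

# backward of one STS iteration: S = Qhat^T X, Q = softmax(X S_prev^T / sqrt(C))
# dS is the gradient on the updated S; extraQ an optional extra gradient on Q
# (from the token-upsampling path). Returns dX and dS_prev.
.sts_iteration_backward <- function(st, X, dS, extraQ = NULL) {
  assoc <- st$assoc
  cs <- assoc$colsum
  live <- cs > 0
  csx <- ifelse(live, cs, 1)
  # S = (Q/cs)^T X  =>  dQhat_ij = X_i . dS_j ; dX += Qhat dS
  dQhat <- .assoc_q_grad(assoc, X, dS)
  # Qhat = Q / cs[j]
  Qhat <- assoc$Q
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    Qhat[ok, o] <- assoc$Q[ok, o] / csx[assoc$idx[ok, o]]
  }
  hatassoc <- assoc; hatassoc$Q <- Qhat
  dX <- .assoc_matvec(hatassoc, dS)
  # column-normalization backward: dQ_ij = (dQhat_ij - t_j) / cs_j,
  # t_j = sum_i Qhat_ij dQhat_ij
  tj <- numeric(assoc$m)
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    if (any(ok)) {
      add <- rowsum(Qhat[ok, o] * dQhat[ok, o], assoc$idx[ok, o])
      j <- as.integer(rownames(add))
      tj[j] <- tj[j] + add
    }
  }
  dQ <- dQhat
  for (o in seq_len(9)) {
    ok <- !is.na(assoc$idx[, o])
    dQ[ok, o] <- (dQhat[ok, o] - tj[assoc$idx[ok, o]]) / csx[assoc$idx[ok, o]]
    dead <- ok & !live[ifelse(is.na(assoc$idx[, o]), 1L, assoc$idx[, o])]
    dQ[dead, o] <- 0
  }
  if (!is.null(extraQ)) dQ <- dQ + extraQ
  # row-softmax backward
  dL <- assoc$Q * (dQ - rowSums(assoc$Q * dQ))
  dL[is.na(assoc$idx)] <- 0
  # logits = X S_prev^T / sqrt(C) on the support
  sc <- 1 / sqrt(ncol(X))
  Sprev <- st$prevS
  lassoc <- assoc; lassoc$Q <- dL
  dX <- dX + .assoc_matvec(lassoc, Sprev) * sc
  dS_prev <- .assoc_tmatvec(lassoc, X) * sc
  # stale super tokens kept their previous value, so their gradient passes on
  if (any(!live)) dS_prev[!live, ] <- dS_prev[!live, , drop = FALSE] +
    dS[!live, , drop = FALSE]
  list(dX = dX, dS_prev = dS_prev)
}
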