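# Minimal layer framework with explicit forward/backward passes.
#
# A module is an environment of class c("sg_<kind>", "sg_module") holding
#   params  : named list of sg_param environments ($value array, $grad array)
#   fixed   : named list of frozen arrays that count as non-trainable params
#   modules : named list of child modules
#   cache   : forward-pass intermediates needed by the backward pass
# Feature maps are arrays with dim c(H, W, C, N).

sg_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "sg_param"
  e
}

sg_module <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- list()
  e$fixed <- list()
  e$modules <- list()
  e$cache <- NULL
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("sg_", .kind), "sg_module")
  e
}

#' Forward pass through a module
#'
#' @param m A module built by one of the `build_*()` constructors.
#' @param x Input array with dim `c(H, W, C, N)` (or a list of such arrays for
#'   multi-input modules like concatenation and the detect head).
#' @param train Logical; use batch statistics and keep backward caches.
#' @return The module output (array, or list for the detect head).
#' @export
sg_forward <- function(m, x, train = FALSE) UseMethod("sg_forward")

#' Backward pass through a module
#'
#' Propagates the gradient of a scalar loss from the module output back to its
#' input, accumulating parameter gradients in place. Requires a preceding
#' [sg_forward()] call with `train = TRUE`.
#'
#' @param m A module.
#' @param gy Gradient array matching the forward output.
#' @return Gradient with respect to the module input.
#' @export
sg_backward <- function(m, gy) UseMethod("sg_backward")

#' Collect all parameters of a module tree
#'
#' @param m A module.
#' @return Flat named list of parameter environments.
#' @export
sg_parameters <- function(m) {
  out <- m$params
  for (nm in names(m$modules)) {
    sub <- sg_parameters(m$modules[[nm]])
    if (length(sub)) names(sub) <- paste0(nm, ".", names(sub))
    out <- c(out, sub)
  }
  out
}

sg_fixed_arrays <- function(m) {
  out <- m$fixed
  for (sub in m$modules) out <- c(out, sg_fixed_arrays(sub))
  out
}

#' Count parameters of a block
#'
#' Counts trainable parameters (convolution weights and biases, normalization
#' scale/shift) and frozen counted parameters (the DFL projection, the
#' super-token unfold/fold kernels). Batch-norm running statistics are buffers
#' and are not counted. Counts are pure functions of the block configuration.
#'
#' @param block A module.
#' @return Named numeric vector `c(trainable = ..., fixed = ...)`.
#' @export
count_params <- function(block) {
  tr <- sum(vapply(sg_parameters(block), function(p) length(p$value), numeric(1)), 0)
  fx <- sum(vapply(sg_fixed_arrays(block), length, numeric(1)), 0)
  c(trainable = tr, fixed = fx)
}

sg_zero_grad <- function(m) {
  for (p in sg_parameters(m)) p$grad <- NULL
  invisible(m)
}

acc_grad <- function(p, g) {
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(p)
}

#' @export
print.sg_module <- function(x, ...) {
  cp <- count_params(x)
  cat(sprintf("<%s> %s trainable + %s fixed parameters\n", x$kind,
              format(cp[["trainable"]], big.mark = ","),
              format(cp[["fixed"]], big.mark = ",")))
  invisible(x)
}

stopifnot_pos_int <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v))
      stop(sprintf("invalid config: `%s` must be a positive integer, got %s",
                   nms[i], deparse(v)), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- primitive layers -------------------------------------------------------

kaiming_init <- function(kh, kw, c_in, c_out) {
  fan_in <- kh * kw * c_in
  array(rnorm(kh * kw * c_in * c_out, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, c_in, c_out))
}

# plain 2-D convolution (optionally biased); same-padding k %/% 2 unless given
layer_conv2d <- function(c_in, c_out, k = 1L, s = 1L, bias = FALSE, pad = NULL) {
  kh <- if (length(k) == 2L) k[1] else k
  kw <- if (length(k) == 2L) k[2] else k
  sh <- if (length(s) == 2L) s[1] else s
  sw <- if (length(s) == 2L) s[2] else s
  if (is.null(pad)) pad <- c(kh %/% 2, kw %/% 2)
  m <- sg_module("conv2d", c_in = c_in, c_out = c_out,
                 kh = kh, kw = kw, sh = sh, sw = sw,
                 ph = pad[1], pw = pad[2])
  m$params$weight <- sg_param(kaiming_init(kh, kw, c_in, c_out))
  if (bias) m$params$bias <- sg_param(numeric(c_out))
  m
}

#' @export
sg_forward.sg_conv2d <- function(m, x, train = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  if (d[3] != m$c_in)
    stop(sprintf("conv2d: expected %d input channels, got %d", m$c_in, d[3]))
  Wm <- matrix(m$params$weight$value, nrow = m$kh * m$kw * m$c_in)
  b <- if (!is.null(m$params$bias)) m$params$bias$value else NULL
  y <- cpp_conv2d_fw(x, d[1], d[2], d[3], d[4], Wm, b,
                     m$kh, m$kw, m$sh, m$sw, m$ph, m$pw)
  if (train) m$cache <- list(x = x, din = d)
  y
}

#' @export
sg_backward.sg_conv2d <- function(m, gy) {
  cc <- m$cache
  Wm <- matrix(m$params$weight$value, nrow = m$kh * m$kw * m$c_in)
  bw <- cpp_conv2d_bw(cc$x, Wm, gy, cc$din[1], cc$din[2], cc$din[3], cc$din[4],
                      m$kh, m$kw, m$sh, m$sw, m$ph, m$pw,
                      need_bias = !is.null(m$params$bias))
  acc_grad(m$params$weight, array(bw$dW, dim = dim(m$params$weight$value)))
  if (!is.null(m$params$bias)) acc_grad(m$params$bias, bw$db)
  bw$dx
}

# batch normalization over (H, W, N) per channel
layer_batchnorm <- function(c, eps = 1e-3, momentum = 0.1) {
  m <- sg_module("batchnorm", c = c, eps = eps, momentum = momentum)
  m$params$gamma <- sg_param(rep(1, c))
  m$params$beta <- sg_param(numeric(c))
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m
}

.bn_channel_stats <- function(x, d) {
  xm <- matrix(x, nrow = d[1] * d[2])           # (H*W) x (C*N)
  mu_cn <- matrix(colMeans(xm), d[3], d[4])
  m2_cn <- matrix(colMeans(xm^2), d[3], d[4])
  mu <- rowMeans(mu_cn)
  list(mean = mu, var = rowMeans(m2_cn) - mu^2)
}

# per-channel vector expanded over (H, W); recycling covers the batch dim
.per_channel <- function(v, d) rep(v, each = d[1] * d[2])

#' @export
sg_forward.sg_batchnorm <- function(m, x, train = FALSE) {
  d <- dim(x)
  if (train) {
    st <- .bn_channel_stats(x, d)
    nE <- d[1] * d[2] * d[4]
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * st$mean
    m$running_var <- (1 - m$momentum) * m$running_var +
      m$momentum * st$var * nE / max(nE - 1, 1)
    mu <- st$mean; va <- st$var
  } else {
    mu <- m$running_mean; va <- m$running_var
  }
  inv <- 1 / sqrt(va + m$eps)
  xhat <- (x - .per_channel(mu, d)) * .per_channel(inv, d)
  y <- xhat * .per_channel(m$params$gamma$value, d) +
    .per_channel(m$params$beta$value, d)
  dim(y) <- d
  if (train) m$cache <- list(xhat = xhat, inv = inv, d = d)
  y
}

.sum_channel <- function(x, d) {
  # sum over H, W, N per channel
  xm <- matrix(x, nrow = d[1] * d[2])
  rowSums(matrix(colSums(xm), d[3], d[4]))
}

#' @export
sg_backward.sg_batchnorm <- function(m, gy) {
  cc <- m$cache; d <- cc$d
  nE <- d[1] * d[2] * d[4]
  dgamma <- .sum_channel(gy * cc$xhat, d)
  dbeta <- .sum_channel(gy, d)
  acc_grad(m$params$gamma, dgamma)
  acc_grad(m$params$beta, dbeta)
  g <- .per_channel(m$params$gamma$value * cc$inv, d)
  gx <- g * (gy - .per_channel(dbeta / nE, d) -
               cc$xhat * .per_channel(dgamma / nE, d))
  dim(gx) <- d
  gx
}

# group normalization over (H, W, channels-in-group) per sample
layer_groupnorm <- function(c, groups, eps = 1e-5) {
  if (c %% groups != 0) stop("groupnorm: channels not divisible by groups")
  m <- sg_module("groupnorm", c = c, groups = groups, eps = eps)
  m$params$gamma <- sg_param(rep(1, c))
  m$params$beta <- sg_param(numeric(c))
  m
}

#' @export
sg_forward.sg_groupnorm <- function(m, x, train = FALSE) {
  d <- dim(x)
  cg <- m$c %/% m$groups
  gsz <- d[1] * d[2] * cg
  xm <- matrix(x, nrow = gsz)                    # gsz x (groups*N)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  inv <- 1 / sqrt(va + m$eps)
  xhat <- (xm - rep(mu, each = gsz)) * rep(inv, each = gsz)
  y <- array(xhat, dim = d) * .per_channel_n(m$params$gamma$value, d) +
    .per_channel_n(m$params$beta$value, d)
  if (train) m$cache <- list(xhat = xhat, inv = inv, d = d, gsz = gsz)
  dim(y) <- d
  y
}

.per_channel_n <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

#' @export
sg_backward.sg_groupnorm <- function(m, gy) {
  cc <- m$cache; d <- cc$d; gsz <- cc$gsz
  xhat_arr <- array(cc$xhat, dim = d)
  dgamma <- .sum_channel(gy * xhat_arr, d)
  dbeta <- .sum_channel(gy, d)
  acc_grad(m$params$gamma, dgamma)
  acc_grad(m$params$beta, dbeta)
  gym <- matrix(gy * .per_channel_n(m$params$gamma$value, d), nrow = gsz)
  s1 <- colMeans(gym)
  s2 <- colMeans(gym * cc$xhat)
  gx <- (gym - rep(s1, each = gsz) - cc$xhat * rep(s2, each = gsz)) *
    rep(cc$inv, each = gsz)
  dim(gx) <- d
  gx
}

# SiLU activation x * sigmoid(x)
layer_silu <- function() sg_module("silu")

#' @export
sg_forward.sg_silu <- function(m, x, train = FALSE) {
  s <- 1 / (1 + exp(-x))
  if (train) m$cache <- list(x = x, s = s)
  x * s
}

#' @export
sg_backward.sg_silu <- function(m, gy) {
  cc <- m$cache
  gy * (cc$s * (1 + cc$x * (1 - cc$s)))
}

# ---- array helpers ----------------------------------------------------------

cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (x in xs) {
    cx <- dim(x)[3]
    out[, , at + seq_len(cx), ] <- x
    at <- at + cx
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0
  lapply(sizes, function(cx) {
    sl <- x[, , at + seq_len(cx), , drop = FALSE]
    at <<- at + cx
    sl
  })
}

upsample_nearest2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample_nearest2_backward <- function(gy) {
  d <- dim(gy)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  gy[i1, j1, , , drop = FALSE] + gy[i1, j2, , , drop = FALSE] +
    gy[i2, j1, , , drop = FALSE] + gy[i2, j2, , , drop = FALSE]
}
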