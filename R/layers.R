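# Dense tensor primitives used by the network forward/backward passes.
#
# Tensors are base-R arrays laid out (N, H, W, C): the batch index is
# fastest, so a matrix view of dim (N*H*W, C) is free (column-major) and the
# compiled kernels vectorize over the batch. Convolution and pooling loops
# live in src/snn_ops.cpp; batch normalization stays in R (cheap, and only
# the feedforward topology uses it).

# x: (N, H, W, Cin); Wk: (k, k, Cin, Cout); bias: length Cout.
conv_forward <- function(x, Wk, bias, keep_col = FALSE) {
  d <- dim(x); dk <- dim(Wk)
  y <- cpp_conv_fwd(x, Wk, bias, d[1], d[2], d[3], d[4], dk[1], dk[4])
  dim(y) <- c(d[1], d[2], d[3], dk[4])
  list(y = y)
}

conv_backward <- function(dy, x, Wk, need_dx = TRUE) {
  d <- dim(x); dk <- dim(Wk)
  r <- cpp_conv_bwd(dy, x, Wk, d[1], d[2], d[3], d[4], dk[1], dk[4], need_dx)
  gW <- r$gW; dim(gW) <- dk
  dx <- NULL
  if (need_dx) { dx <- r$dx; dim(dx) <- d }
  list(gW = gW, gb = r$gb, dx = dx)
}

# Max pooling, stride = size; records the argmax for the backward scatter.
pool_forward <- function(x, s) {
  if (s == 1L) return(list(y = x, amax = NULL, in_len = NULL))
  d <- dim(x)
  r <- cpp_pool_fwd(x, d[1], d[2], d[3], d[4], s)
  y <- r$y
  dim(y) <- c(d[1], d[2] %/% s, d[3] %/% s, d[4])
  list(y = y, amax = r$amax, in_len = length(x))
}

pool_backward <- function(dy, amax, in_len) {
  if (is.null(amax)) return(dy)
  cpp_pool_bwd(dy, amax, in_len)
}

# Per-channel batch normalization over the (N, H, W) axes of one timestep's
# tensor. `training = TRUE` uses batch statistics and updates the running
# estimates in `rs` (an environment with mean/var/momentum); otherwise the
# frozen running statistics are used.
bn_forward <- function(x, gamma, beta, rs, training, eps = 1e-5) {
  d <- dim(x); C <- d[4]; m <- prod(d[1:3])
  xm <- matrix(x, m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    va <- colSums(xc * xc) / m
    rs$mean <- (1 - rs$momentum) * rs$mean + rs$momentum * mu
    rs$var <- (1 - rs$momentum) * rs$var + rs$momentum * va * m / max(m - 1, 1)
  } else {
    mu <- rs$mean
    va <- rs$var
    xc <- xm - rep(mu, each = m)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = m)
  y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, training = training)
}

bn_backward <- function(dy, cache, gamma) {
  d <- dim(dy); C <- d[4]; m <- prod(d[1:3])
  dym <- matrix(dy, m, C)
  ggamma <- colSums(dym * cache$xhat)
  gbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = m)
  if (cache$training) {
    # full batch-statistics backward
    t1 <- colMeans(dxhat)
    t2 <- colMeans(dxhat * cache$xhat)
    dx <- (dxhat - rep(t1, each = m) - cache$xhat * rep(t2, each = m)) *
      rep(cache$istd, each = m)
  } else {
    dx <- dxhat * rep(cache$istd, each = m)
  }
  dim(dx) <- d
  list(dx = dx, ggamma = ggamma, gbeta = gbeta)
}
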