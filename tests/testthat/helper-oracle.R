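# Independent oracles used across the test files.

# Closed-form inter-spike interval of a leak-free-threshold LIF neuron under
# constant suprathreshold current (v_leak = 0, reset 0):
# T = tau * ln(I / (I - v_th)) frames, rate = 1/T.
closed_form_rate <- function(I, tau, v_th = 1) {
  r <- numeric(length(I))
  sup <- I > v_th
  r[sup] <- 1 / (tau * log(I[sup] / (I[sup] - v_th)))
  r
}

# Naive loop convolution (same padding, stride 1) on (N, H, W, Cin) input —
# written directly from the definition, independent of the package kernels.
naive_conv <- function(x, Wk, bias) {
  d <- dim(x); dk <- dim(Wk)
  N <- d[1]; H <- d[2]; W <- d[3]; Cin <- d[4]
  k <- dk[1]; Cout <- dk[4]; pad <- (k - 1) / 2
  y <- array(0, c(N, H, W, Cout))
  for (n in 1:N) for (h in 1:H) for (w in 1:W) for (co in 1:Cout) {
    acc <- bias[co]
    for (dh in 1:k) for (dw in 1:k) for (ci in 1:Cin) {
      hh <- h + dh - 1 - pad; ww <- w + dw - 1 - pad
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        acc <- acc + x[n, hh, ww, ci] * Wk[dh, dw, ci, co]
    }
    y[n, h, w, co] <- acc
  }
  y
}

# Central finite differences of a scalar function of one parameter tensor.
fd_grad <- function(f, par, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    p1 <- par; p1[i] <- p1[i] + eps
    p2 <- par; p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}

# Loss of a network as a function of one (replaced) parameter tensor.
net_loss_fn <- function(net, pname, batch, c = 0, spec = NULL, phi = NULL) {
  function(par) {
    n2 <- net
    n2$params[[pname]] <- par
    fw <- contextsnn:::snn_forward(n2, batch$frames, c = c, spec = spec,
                                   phi = phi, train = TRUE)
    contextsnn:::loss_and_dout(fw, batch, n2$config$n_out)$loss
  }
}

# Analytic gradients of the same loss.
net_analytic_grads <- function(net, batch, c = 0, spec = NULL, phi = NULL) {
  fw <- contextsnn:::snn_forward(net, batch$frames, c = c, spec = spec,
                                 phi = phi, train = TRUE)
  ld <- contextsnn:::loss_and_dout(fw, batch, net$config$n_out)
  contextsnn:::snn_backward(net, fw, ld$d_out)
}

# Tiny deterministic tracking batch for gradient checks.
tiny_tracking_batch <- function(N = 2, T = 5, H = 6, W = 6, seed = 42) {
  withr_seed <- contextsnn:::with_seed
  withr_seed(seed, {
    frames <- array(rnorm(N * T * H * W, sd = 0.5), c(N, T, H, W))
    target <- array(runif(N * T * 2), c(N, T, 2))
    list(frames = frames, target = target, loss = "mse")
  })
}

tiny_class_batch <- function(N = 3, H = 6, W = 6, K = 3, seed = 43) {
  contextsnn:::with_seed(seed, {
    frames <- array(rnorm(N * H * W, sd = 0.5), c(N, H, W))
    list(frames = frames, target = sample.int(K, N, replace = TRUE),
         loss = "ce")
  })
}
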