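# Correctness of the compiled tensor kernels and of the assembled BPTT
# gradients.

test_that("compiled convolution matches a naive-loop reference", {
  set.seed(10)
  for (k in c(1, 3)) {
    x <- array(rnorm(2 * 5 * 6 * 3), c(2, 5, 6, 3))
    Wk <- array(rnorm(k * k * 3 * 4), c(k, k, 3, 4))
    b <- rnorm(4)
    y <- contextsnn:::conv_forward(x, Wk, b)$y
    expect_equal(y, naive_conv(x, Wk, b), tolerance = 1e-12)
  }
})

test_that("convolution backward agrees with the Jacobian of the forward map", {
  set.seed(11)
  x <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  Wk <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  bk <- contextsnn:::conv_backward(dy, x, Wk, need_dx = TRUE)
  # conv is linear in both x and W: gradients are exact inner products with
  # basis perturbations of the forward map
  for (i in sample(length(Wk), 6)) {
    Wk2 <- Wk; Wk2[i] <- Wk2[i] + 1
    dir <- contextsnn:::conv_forward(x, Wk2, b)$y -
      contextsnn:::conv_forward(x, Wk, b)$y
    expect_equal(bk$gW[i], sum(dir * dy), tolerance = 1e-9)
  }
  for (i in sample(length(x), 6)) {
    x2 <- x; x2[i] <- x2[i] + 1
    dir <- contextsnn:::conv_forward(x2, Wk, b)$y -
      contextsnn:::conv_forward(x, Wk, b)$y
    expect_equal(bk$dx[i], sum(dir * dy), tolerance = 1e-9)
  }
  expect_equal(bk$gb, colSums(matrix(dy, 32, 3)), tolerance = 1e-12)
})

test_that("max pooling takes blockwise maxima and routes gradients to argmax", {
  set.seed(12)
  x <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  pf <- contextsnn:::pool_forward(x, 2)
  expect_equal(dim(pf$y), c(2, 2, 2, 3))
  for (n in 1:2) for (c in 1:3) for (i in 1:2) for (j in 1:2)
    expect_equal(pf$y[n, i, j, c],
                 max(x[n, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
  dy <- array(rnorm(length(pf$y)), dim(pf$y))
  dx <- contextsnn:::pool_backward(dy, pf$amax, pf$in_len)
  expect_equal(sum(dx != 0), length(dy))
  expect_equal(sum(dx), sum(dy), tolerance = 1e-12)
  # pool size 1 is the identity
  pf1 <- contextsnn:::pool_forward(x, 1)
  expect_identical(pf1$y, x)
})

test_that("batch normalization forward/backward pass a finite-difference check", {
  set.seed(13)
  d <- c(3, 4, 4, 2)
  x <- array(rnorm(prod(d)), d)
  gamma <- c(1.3, 0.7); beta <- c(0.2, -0.1)
  dy <- array(rnorm(prod(d)), d)
  for (training in c(TRUE, FALSE)) {
    rs <- new.env(); rs$mean <- c(0.1, -0.2); rs$var <- c(1.5, 0.8); rs$momentum <- 0.1
    fwd <- function(xx) {
      r2 <- new.env(); r2$mean <- rs$mean; r2$var <- rs$var; r2$momentum <- 0.1
      sum(contextsnn:::bn_forward(xx, gamma, beta, r2, training)$y * dy)
    }
    cache <- contextsnn:::bn_forward(x, gamma, beta, rs, training)
    bk <- contextsnn:::bn_backward(dy, cache, gamma)
    idx <- sample(length(x), 8)
    expect_equal(bk$dx[idx], fd_grad(fwd, x, idx), tolerance = 1e-6)
    fwd_g <- function(gg) {
      r2 <- new.env(); r2$mean <- c(0.1, -0.2); r2$var <- c(1.5, 0.8); r2$momentum <- 0.1
      sum(contextsnn:::bn_forward(x, gg, beta, r2, training)$y * dy)
    }
    expect_equal(bk$ggamma, fd_grad(fwd_g, gamma, 1:2), tolerance = 1e-6)
    expect_equal(bk$gbeta, colSums(matrix(dy, prod(d[1:3]), 2)), tolerance = 1e-9)
  }
})

# Full-network gradient checks. With a very steep surrogate the analytic
# gradient coincides with the local derivative of the piecewise-smooth loss
# (the spike-jump contribution is numerically zero away from threshold), so
# central finite differences are a valid oracle for every smooth path:
# membrane carry, reset gating, convolutions (feedforward and recurrent),
# batch norm, pooling, readout, perturbation chain rule and tau-mode
# modulation. The surrogate path itself is checked analytically below.
fd_check_network <- function(topology, mod_mode, head, perturbed = FALSE,
                             seed = 21, n_coord = 5, tol = 1e-4) {
  K <- 3
  cfg <- network_config(topology, c(6, 6), channels = c(2, 3),
                        pools = c(2, 1), head = head,
                        n_out = if (head == "tracking") 2 else K,
                        timesteps = 5, beta = 1e9, input_gain = 1)
  variant <- if (mod_mode == "none") "base" else "context"
  net <- build_network(cfg, variant, mod_mode, init_seed = seed)
  net$bn_frozen <- TRUE   # frozen normalization statistics (adapt phase)
  for (nm in names(net$bn)) {
    C <- length(net$bn[[nm]]$mean)
    net$bn[[nm]] <- list(mean = seq(-0.1, 0.1, length.out = C),
                         var = seq(0.8, 1.2, length.out = C))
  }
  batch <- if (head == "tracking") tiny_tracking_batch(seed = seed + 1)
           else tiny_class_batch(K = K, seed = seed + 1)
  cc <- if (mod_mode == "none" && !perturbed) 0 else 0.6
  spec <- if (perturbed) gaussian_spec() else NULL
  phi <- if (perturbed) network_phi(net, perturbation_draw(seed + 2)) else NULL
  an <- net_analytic_grads(net, batch, c = cc, spec = spec, phi = phi)
  set.seed(seed + 3)
  for (pname in names(net$params)) {
    par <- net$params[[pname]]
    idx <- sample(length(par), min(n_coord, length(par)))
    fd <- fd_grad(net_loss_fn(net, pname, batch, c = cc, spec = spec,
                              phi = phi), par, idx)
    ok <- abs(an[[pname]][idx] - fd) <= tol * (1 + abs(fd))
    expect_true(all(ok),
                label = sprintf("%s/%s/%s gradient of %s (max err %.2g)",
                                topology, mod_mode, head, pname,
                                max(abs(an[[pname]][idx] - fd))))
  }
}

test_that("BPTT gradients match finite differences: recurrent tracking net", {
  fd_check_network("recurrent", "none", "tracking")
})

test_that("BPTT gradients match finite differences: feedforward classifier", {
  fd_check_network("feedforward", "none", "classification")
})

test_that("BPTT gradients match finite differences under perturbed weights", {
  fd_check_network("recurrent", "none", "tracking", perturbed = TRUE, seed = 31)
})

test_that("BPTT gradients match finite differences for tau-mode projections", {
  # tau modulation reaches the loss through the membrane (not the spike
  # jump), so finite differences check the p gradients directly
  fd_check_network("recurrent", "tau", "tracking", seed = 41)
  fd_check_network("feedforward", "tau", "classification", seed = 43)
})

test_that("threshold-mode projection gradient matches the hand-derived chain", {
  # single unit, one timestep: I constant, v' = alpha I crosses threshold.
  # Loss = readout of the spike; d loss / d p = dL/dz * (-sg) * c with
  # sg = 1/(beta |v' - v_th| + 1)^2. Computed by hand for a 1x1 network.
  cfg <- network_config("recurrent", c(4, 4), channels = 1, pools = 1,
                        head = "tracking", n_out = 2, timesteps = 1,
                        beta = 10, input_gain = 1, tau_m_base = 2)
  net <- build_network(cfg, "context", "threshold", init_seed = 5)
  net$params[["b1.p"]] <- 0.3
  cc <- 0.5
  batch <- list(frames = array(0.9, c(1, 1, 4, 4)),
                target = array(0.2, c(1, 1, 2)), loss = "mse")
  an <- net_analytic_grads(net, batch, c = cc)
  # forward by hand
  v_th <- 1 + 0.3 * cc
  alpha <- 1 / 2
  vpre <- alpha * 0.9 * as.numeric(naive_conv(array(1, c(1, 4, 4, 1)),
                                              net$params[["b1.W"]], 0))
  z <- (vpre > v_th) + 0
  sg <- 1 / (10 * abs(vpre - v_th) + 1)^2
  # readout: LI over fc of flattened z; dL/dz_j = a_out * 2*(out - tgt)/(N*T*2) %*% W_fc[j,]
  a_out <- 1 / 4
  fcW <- net$params[["fc.W"]]
  out <- a_out * (as.numeric(z) %*% fcW + net$params[["fc.b"]])
  dl_dout <- out - 0.2   # d mean(err^2) / d out over the 2 outputs
  dl_dz <- as.numeric(fcW %*% t(dl_dout)) * a_out
  gp_hand <- -cc * sum(dl_dz * sg)
  expect_equal(an[["b1.p"]], gp_hand, tolerance = 1e-10)
})
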