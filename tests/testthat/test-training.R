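toy_train_data <- function(n = 40, seed = 1)
  generate_toy_classification(
    toyclass_config(n_classes = 3, height = 8, width = 8, noise_sigma = 0.05,
                    timesteps = 8, seed = seed, template_seed = 77), n)

toy_net <- function(seed = 1, variant = "base", mod = "none")
  build_network(network_config("recurrent", c(8, 8), channels = c(2, 4),
                               pools = c(2, 1), head = "classification",
                               n_out = 3, timesteps = 8, beta = 10),
                variant, mod, init_seed = seed, spike_rate_init = 0.005)

test_that("pretraining the base model beats chance on a separable task", {
  d <- toy_train_data()
  fit <- pretrain(toy_net(), d, train_config(epochs = 12, lr = 0.05,
                                             batch_size = 10, seed = 3))
  expect_s3_class(fit, "snn_fit")
  expect_true(all(is.finite(fit$history$loss)))
  expect_gt(tail(fit$history$metric, 1), 1 / 3)
  expect_true(fit$network$bn_frozen)
  s <- summary(fit)
  expect_equal(s$epochs, 12)
  expect_output(print(s), "Training summary")
})

test_that("identical seeds give identical trained weights", {
  d <- toy_train_data()
  cfg <- train_config(epochs = 3, lr = 0.05, batch_size = 10, seed = 11)
  f1 <- pretrain(toy_net(), d, cfg)
  f2 <- pretrain(toy_net(), d, cfg)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$history, f2$history)
  a1 <- adapt_train(f1, "context", "threshold", c_max = 1, d, cfg, init_seed = 2)
  a2 <- adapt_train(f2, "context", "threshold", c_max = 1, d, cfg, init_seed = 2)
  expect_identical(a1$network$params, a2$network$params)
})

test_that("pretraining requires the base variant and adapt rejects off-grid c_max", {
  d <- toy_train_data()
  cfg <- train_config(epochs = 1, batch_size = 10)
  expect_error(pretrain(toy_net(variant = "sham", mod = "tau"), d, cfg), "base")
  f <- pretrain(toy_net(), d, cfg)
  expect_error(adapt_train(f, "perturbed", "none", c_max = 0.55, d, cfg),
               "level grid")
  expect_error(adapt_train(f, "base", "none", c_max = 0, d, cfg), "variant")
})

test_that("a level-0 perturbation draw leaves loss and gradients unchanged", {
  d <- toy_train_data()
  net <- toy_net()
  batch <- contextsnn:::get_batch(d, 1:8)
  phi <- network_phi(net, perturbation_draw(5))
  g0 <- contextsnn:::snn_loss_grad(net, batch, c = 0, spec = gaussian_spec(),
                                   phi = phi, train_p = FALSE)
  g1 <- contextsnn:::snn_loss_grad(net, batch, c = 0, spec = NULL, phi = NULL,
                                   train_p = FALSE)
  expect_identical(g0$loss, g1$loss)
  expect_identical(g0$grads, g1$grads)
})

test_that("gradient hygiene: projections receive gradients only when trained", {
  d <- toy_train_data()
  net <- toy_net(variant = "context", mod = "threshold")
  batch <- contextsnn:::get_batch(d, 1:8)
  g_on <- contextsnn:::snn_loss_grad(net, batch, c = 0.7, train_p = TRUE)
  g_off <- contextsnn:::snn_loss_grad(net, batch, c = 0.7, train_p = FALSE)
  expect_true(any(g_on$grads[["b1.p"]] != 0) || any(g_on$grads[["b2.p"]] != 0))
  expect_true(all(g_off$grads[["b1.p"]] == 0) && all(g_off$grads[["b2.p"]] == 0))
})

test_that("the plateau schedule halves the rate only after sustained stalls", {
  d <- toy_train_data(n = 20)
  # zero learning rate cannot be configured (lr > 0), so force a stall with a
  # tiny rate and check the patience bookkeeping on the recorded history
  fit <- pretrain(toy_net(), d, train_config(epochs = 14, lr = 1e-9,
                                             patience = 5, batch_size = 20,
                                             seed = 2))
  lrs <- fit$history$lr
  expect_true(all(diff(lrs) <= 0))                     # non-increasing
  expect_lte(sum(diff(lrs) < 0), 14 %/% 5)             # at most every 5 epochs
  halves <- which(diff(lrs) < 0)
  if (length(halves) >= 2) expect_true(all(diff(halves) >= 5))
})

test_that("adapt training of sham and context trains p; perturbed leaves none", {
  d <- toy_train_data()
  pre <- pretrain(toy_net(), d, train_config(epochs = 2, lr = 0.05,
                                             batch_size = 10, seed = 4))
  cfg <- train_config(epochs = 2, lr = 0.05, batch_size = 10, seed = 5,
                      p_lr_scale = 25)
  sham <- adapt_train(pre, "sham", "threshold", c_max = 1, d, cfg, init_seed = 3)
  expect_false(identical(sham$network$params[["b1.p"]],
                         build_network(sham$network$config, "sham", "threshold",
                                       init_seed = 3)$params[["b1.p"]]))
  pert <- adapt_train(pre, "perturbed", "none", c_max = 1, d, cfg)
  expect_null(pert$network$params[["b1.p"]])
  # weights stay perturbation-free for sham: identical to a context run's
  # weight trajectory is not required, but the run must be reproducible
  sham2 <- adapt_train(pre, "sham", "threshold", c_max = 1, d, cfg, init_seed = 3)
  expect_identical(sham$network$params, sham2$network$params)
})

test_that("divergence aborts with a diagnostic naming epoch and seed", {
  d <- toy_train_data(n = 20)
  net <- toy_net()
  net$params[["b1.W"]][] <- 1e308   # overflows the first-layer currents
  expect_error(
    pretrain(net, d, train_config(epochs = 1, lr = 1, batch_size = 20, seed = 6)),
    "non-finite|diverged")
})
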