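#' Training configuration
#'
#' Both training phases use backpropagation through time with stochastic
#' gradient descent plus momentum, the SuperSpike surrogate gradient across
#' the spike nonlinearity, and a plateau learning-rate schedule (halved after
#' `patience` consecutive non-improving epochs). The loss follows the task
#' head: cross-entropy on the final-timestep logits for classification,
#' per-timestep mean squared error for tracking.
#'
#' @param epochs training epochs (paper-scale default 100; desk-scale presets
#'   use far fewer).
#' @param lr initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param patience epochs without improvement before the learning rate is
#'   multiplied by `lr_factor`.
#' @param lr_factor plateau decay factor.
#' @param batch_size minibatch size; one minibatch is one "trial" for the
#'   purpose of trial-frozen perturbation draws.
#' @param context_sampling `"uniform"` samples the context level uniformly
#'   from the grid restricted to `[0, c_max]` on every batch; `"fixed"`
#'   always trains at `c_max`.
#' @param p_lr_scale multiplier on the learning rate of the adaptive
#'   projections `p`. The projections live in different natural units than
#'   the weights (volts of threshold shift, or frames of time-constant
#'   shift, per unit of context), so their useful step size differs from the
#'   weight step size by orders of magnitude; tau-mode projections in
#'   particular move the per-step leak factor only by `c * dt / tau^2` per
#'   unit of p.
#' @param clip global gradient-norm clip (`Inf` to disable).
#' @param seed master seed; shuffling, context sampling and perturbation
#'   draws are all derived from it, so identical seeds give identical
#'   training runs on one thread.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100, lr = 0.001, momentum = 0.9,
                         patience = 10, lr_factor = 0.5, batch_size = 64,
                         context_sampling = c("uniform", "fixed"),
                         p_lr_scale = 1, clip = 5, seed = 1, verbose = FALSE) {
  context_sampling <- match.arg(context_sampling)
  check_that(lr > 0, "learning rate must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 patience = as.integer(patience), lr_factor = lr_factor,
                 batch_size = as.integer(batch_size),
                 context_sampling = context_sampling, clip = clip,
                 p_lr_scale = p_lr_scale,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# Extract one training batch: frames plus loss targets (normalized
# coordinates for tracking, integer labels for classification).
get_batch <- function(data, idx) {
  if (data$task == "sot") {
    H <- data$config$height; W <- data$config$width
    tg <- data$tracks[idx, , , drop = FALSE]
    tg[, , 1] <- tg[, , 1] / (W - 1)
    tg[, , 2] <- tg[, , 2] / (H - 1)
    list(frames = data$frames[idx, , , , drop = FALSE], target = tg,
         loss = "mse")
  } else {
    list(frames = data$frames[idx, , , drop = FALSE],
         target = data$labels[idx], loss = "ce")
  }
}

# Loss value and dL/d outputs for a forward pass.
loss_and_dout <- function(fw, batch, n_out) {
  N <- fw$N; T <- fw$T
  d_out <- array(0, c(N, T, n_out))
  if (batch$loss == "ce") {
    logits <- matrix(fw$outputs[, T, ], N, n_out)
    m <- apply(logits, 1, max)
    ex <- exp(logits - m)
    sm <- ex / rowSums(ex)
    y <- matrix(0, N, n_out)
    y[cbind(seq_len(N), batch$target)] <- 1
    loss <- -mean(log(pmax(sm[cbind(seq_len(N), batch$target)], 1e-12)))
    d_out[, T, ] <- (sm - y) / N
    metric <- mean(max.col(logits, ties.method = "first") == batch$target)
  } else {
    err <- fw$outputs - batch$target
    loss <- mean(err^2)
    d_out <- 2 * err / length(err)
    metric <- loss
  }
  list(loss = loss, d_out = d_out, metric = metric)
}

# One forward + backward on a batch. Returns loss, metric and gradients for
# the ideal parameters.
snn_loss_grad <- function(net, batch, c = 0, spec = NULL, phi = NULL,
                          bn_env = NULL, bn_training = FALSE, train_p = TRUE) {
  fw <- snn_forward(net, batch$frames, c = c, spec = spec, phi = phi,
                    train = TRUE, bn_training = bn_training, bn_env = bn_env)
  ld <- loss_and_dout(fw, batch, net$config$n_out)
  grads <- snn_backward(net, fw, ld$d_out, train_p = train_p)
  list(loss = ld$loss, metric = ld$metric, grads = grads)
}

global_norm <- function(grads)
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))

# The shared SGD-with-momentum training loop behind pretrain() and
# adapt_train().
run_training <- function(net, data, config, spec = NULL, c_max = 0,
                         perturb_in_training = FALSE, bn_training = FALSE,
                         train_p = FALSE, phase = "pretrain") {
  n <- n_samples(data)
  check_that(n >= config$batch_size || n >= 1, "empty dataset")
  bs <- min(config$batch_size, n)
  vel <- lapply(net$params, function(p) p * 0)
  lr <- config$lr
  best <- Inf; stall <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     metric = numeric(0), lr = numeric(0))
  levels_all <- context_levels(spec)
  if (!is.null(spec)) {
    check_that(any(abs(levels_all - c_max) < 1e-9) || c_max == 0,
               "c_max must lie on the perturbation level grid")
    levels_tr <- levels_all[levels_all <= c_max + 1e-9]
  } else levels_tr <- 0
  bn_env <- new.env(parent = emptyenv())
  for (nm in names(net$bn)) {
    e <- new.env(parent = emptyenv())
    e$mean <- net$bn[[nm]]$mean; e$var <- net$bn[[nm]]$var; e$momentum <- 0.1
    assign(nm, e, envir = bn_env)
  }
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- n %/% bs
    ep_loss <- 0; ep_metric <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1) * bs + 1):(ib * bs)]
      batch <- get_batch(data, idx)
      cc <- if (config$context_sampling == "fixed") c_max
            else levels_tr[sample.int(length(levels_tr), 1)]
      phi <- NULL
      if (perturb_in_training) {
        dseed <- sample.int(.Machine$integer.max - 1L, 1L)
        phi <- network_phi(net, perturbation_draw(dseed))
      }
      sg <- snn_loss_grad(net, batch, c = cc, spec = spec, phi = phi,
                          bn_env = bn_env, bn_training = bn_training,
                          train_p = train_p)
      if (!is.finite(sg$loss))
        stop(sprintf("training diverged (loss %g) at epoch %d, seed %d",
                     sg$loss, ep, config$seed), call. = FALSE)
      g <- sg$grads
      gn <- global_norm(g)
      if (is.finite(config$clip) && gn > config$clip)
        g <- lapply(g, function(x) x * (config$clip / gn))
      for (nm in names(net$params)) {
        vel[[nm]] <- config$momentum * vel[[nm]] + g[[nm]]
        sc <- if (endsWith(nm, ".p")) config$p_lr_scale else 1
        net$params[[nm]] <- net$params[[nm]] - lr * sc * vel[[nm]]
      }
      ep_loss <- ep_loss + sg$loss; ep_metric <- ep_metric + sg$metric
    }
    ep_loss <- ep_loss / nb; ep_metric <- ep_metric / nb
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss,
                                   metric = ep_metric, lr = lr))
    if (config$verbose)
      message(sprintf("[%s] epoch %d/%d loss %.5f metric %.4f lr %.2g",
                      phase, ep, config$epochs, ep_loss, ep_metric, lr))
    if (ep_loss < best - 1e-8) { best <- ep_loss; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= config$patience) { lr <- lr * config$lr_factor; stall <- 0L }
    }
  }
  # write back running batch-norm statistics
  for (nm in names(net$bn)) {
    e <- get(nm, envir = bn_env)
    net$bn[[nm]]$mean <- e$mean; net$bn[[nm]]$var <- e$var
  }
  list(net = net, history = hist)
}

#' Pretrain the base model
#'
#' Phase one of the two-phase protocol: the base network is trained without
#' perturbations or context-dependent mechanisms until the weights converge
#' under ideal conditions. Batch-normalization statistics accumulated during
#' pretraining are frozen afterwards so later perturbations cannot leak into
#' the normalization constants.
#'
#' @param net an `snn_network` with `variant = "base"`.
#' @param data an `snn_data` training set.
#' @param config a [train_config()].
#' @return object of class `snn_fit`.
#' @export
pretrain <- function(net, data, config) {
  check_that(inherits(net, "snn_network") && net$variant == "base",
             "pretraining requires the base variant")
  rt <- run_training(net, data, config, spec = NULL, c_max = 0,
                     perturb_in_training = FALSE, bn_training = TRUE,
                     train_p = FALSE, phase = "pretrain")
  rt$net$bn_frozen <- TRUE
  new_snn_fit(rt$net, rt$history, config, phase = "pretrain", c_max = 0,
              spec = NULL)
}

#' Re-cast a (pretrained) network as another experimental variant
#'
#' Copies the weights and frozen normalization statistics into a fresh
#' network of the requested variant, adding freshly initialized modulation
#' projections for sham/context variants. Parameter count therefore exceeds
#' the base network by exactly the number of modulated units.
#'
#' @param net source `snn_network` (typically a pretrained base model).
#' @param variant target variant.
#' @param mod_mode modulation mode for sham/context.
#' @param init_seed seed for the projection initializer.
#' @return an `snn_network`.
#' @export
as_variant <- function(net, variant, mod_mode = "none", init_seed = 1L) {
  out <- build_network(net$config, variant = variant, mod_mode = mod_mode,
                       init_seed = init_seed)
  for (nm in names(net$params)) out$params[[nm]] <- net$params[[nm]]
  out$bn <- net$bn
  out$bn_frozen <- net$bn_frozen
  out
}

#' Adapt-phase training of an experimental variant
#'
#' Phase two: starting from pretrained weights, each Table-2-style variant is
#' trained further. On every batch a context level is sampled from the
#' perturbation grid restricted to `[0, c_max]`; perturbation-bearing
#' variants (perturbed, context) receive a fresh trial-frozen perturbation
#' draw for that batch, with gradients flowing through the perturbed weights
#' to the ideal weights. Modulated variants (sham, context) train the
#' projections `p` jointly with the weights; sham receives the same sampled
#' context but no perturbation.
#'
#' @param pretrained an `snn_fit` from [pretrain()] or an `snn_network`
#'   holding pretrained weights.
#' @param variant `"perturbed"`, `"sham"` or `"context"`.
#' @param mod_mode `"threshold"` or `"tau"` for modulated variants.
#' @param c_max maximum training context level (must lie on the level grid).
#' @param data training set.
#' @param config a [train_config()].
#' @param spec perturbation model, default [gaussian_spec()].
#' @param init_seed seed for the projection initializer.
#' @return an `snn_fit`.
#' @export
adapt_train <- function(pretrained, variant, mod_mode = "none", c_max, data,
                        config, spec = gaussian_spec(), init_seed = 1L) {
  net <- if (inherits(pretrained, "snn_fit")) pretrained$network else pretrained
  check_that(inherits(net, "snn_network"), "pretrained network required")
  check_that(variant %in% c("perturbed", "sham", "context"),
             "adapt phase trains the perturbed, sham or context variants")
  net <- as_variant(net, variant, mod_mode, init_seed = init_seed)
  perturb <- variant %in% c("perturbed", "context")
  train_p <- variant %in% c("sham", "context")
  rt <- run_training(net, data, config, spec = spec, c_max = c_max,
                     perturb_in_training = perturb, bn_training = FALSE,
                     train_p = train_p, phase = paste0("adapt:", variant))
  new_snn_fit(rt$net, rt$history, config, phase = "adapt", c_max = c_max,
              spec = spec)
}

new_snn_fit <- function(net, history, config, phase, c_max, spec) {
  structure(list(network = net, history = history, train_config = config,
                 phase = phase, c_max = c_max,
                 spec_model = if (is.null(spec)) NA_character_ else spec$model),
            class = "snn_fit")
}

#' @export
print.snn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("snn_fit: %s phase, %s variant, %d epochs; final loss %.5f\n",
              x$phase, x$network$variant, nrow(h), h$loss[nrow(h)]))
  print(x$network)
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, ...) {
  h <- object$history
  out <- list(phase = object$phase, variant = object$network$variant,
              mod_mode = object$network$mod_mode, c_max = object$c_max,
              epochs = nrow(h), final_loss = h$loss[nrow(h)],
              best_loss = min(h$loss), final_lr = h$lr[nrow(h)],
              n_parameters = n_parameters(object$network))
  class(out) <- "summary.snn_fit"
  out
}

#' @export
print.summary.snn_fit <- function(x, ...) {
  cat(sprintf(
    "Training summary (%s / %s%s, c_max = %g)\n  epochs %d, final loss %.5f, best loss %.5f, final lr %.3g, %d parameters\n",
    x$phase, x$variant,
    if (x$mod_mode != "none") paste0(" + ", x$mod_mode) else "",
    x$c_max, x$epochs, x$final_loss, x$best_loss, x$final_lr, x$n_parameters))
  invisible(x)
}

#' @export
coef.snn_fit <- function(object, ...) object$network$params

#' @export
predict.snn_fit <- function(object, frames, ...) predict(object$network, frames, ...)

#' @export
plot.snn_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = sprintf("%s (%s)", x$phase, x$network$variant), ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the ideal weights, learned projection vectors,
#' normalization statistics and the network configuration, together with a
#' manifest recording variant, modulation mode, seed and the training
#' perturbation maximum. Key layout: `network$params[["b<k>.W"]]`,
#' `[["b<k>.Wrec"]]`, `[["b<k>.p"]]`, `[["fc.W"]]`, etc.
#'
#' @param fit an `snn_fit` (or bare `snn_network`).
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored object.
#' @export
save_checkpoint <- function(fit, path) {
  net <- if (inherits(fit, "snn_fit")) fit$network else fit
  manifest <- list(variant = net$variant, mod_mode = net$mod_mode,
                   init_seed = net$init_seed,
                   c_max = if (inherits(fit, "snn_fit")) fit$c_max else NA,
                   package_version = as.character(utils::packageVersion("contextsnn")))
  saveRDS(list(object = fit, manifest = manifest), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$object
}
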