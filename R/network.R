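#' Specification of one convolutional SNN block
#'
#' A block is a convolution (same padding, stride 1), optional per-channel
#' batch normalization, a LIF activation layer (optionally context
#' modulated), and max pooling. Recurrent blocks add a second convolution
#' applied to the block's own previous-timestep spikes, entering as an
#' additive current stream; recurrent blocks never use batch normalization
#' (keeping every inter-block tensor binary), feedforward blocks always do.
#'
#' @param out_channels number of output channels.
#' @param kernel odd kernel size.
#' @param pool max-pooling size (1 = no pooling).
#' @param norm logical, batch normalization present.
#' @param recurrent logical, recurrent convolution present.
#' @return object of class `block_spec`.
#' @export
block_spec <- function(out_channels, kernel = 3, pool = 2,
                       norm = TRUE, recurrent = FALSE) {
  check_that(kernel %% 2 == 1, "kernel size must be odd (same padding)")
  check_that(!(norm && recurrent),
             "recurrent blocks do not use batch normalization")
  structure(list(out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 norm = isTRUE(norm), recurrent = isTRUE(recurrent)),
            class = "block_spec")
}

#' Network configuration
#'
#' Describes one of the two supported topologies: a feedforward VGG-like SNN
#' (conv + batch norm + LIF + pool blocks) or a convolutional-recurrent SNN
#' (CRNN blocks without batch norm), both followed by a single flatten +
#' linear + leaky-integrator readout. The readout is non-spiking so spike
#' evidence accumulates over the trial.
#'
#' @param topology `"feedforward"` or `"recurrent"`.
#' @param input_shape `c(H, W)` of input frames (single channel).
#' @param channels output channels per block; spatial resolution decreases
#'   while channel count increases, VGG style.
#' @param pools per-block pooling sizes (recycled).
#' @param kernel convolution kernel size.
#' @param head `"classification"` (logits read from the leaky-integrator
#'   state at the final timestep) or `"tracking"` ((x, y) read per timestep).
#' @param n_out output dimension (classes, or 2 for tracking).
#' @param timesteps presentation length for static-frame tasks; temporal
#'   tasks take T from the data.
#' @param tau_m_base LIF membrane time constant in frames; defaults to 4 for
#'   feedforward and 16 for recurrent networks.
#' @param readout_tau leaky-integrator time constant; defaults to
#'   `tau_m_base` for classification (slow accumulation of spike evidence
#'   over the trial) and to 4 frames for tracking, where the readout must
#'   follow a moving target with little lag.
#' @param input_gain gain of the current injection encoding input frames;
#'   pixel values are multiplied by this gain before entering the first
#'   convolution.
#' @param beta SuperSpike surrogate slope.
#' @param tau_param time-constant parameterization, see [lif_params()].
#' @return object of class `network_config`.
#' @export
network_config <- function(topology = c("feedforward", "recurrent"),
                           input_shape, channels = c(8, 16, 32),
                           pools = 2, kernel = 3,
                           head = c("classification", "tracking"),
                           n_out, timesteps = 32,
                           tau_m_base = NULL, readout_tau = NULL,
                           input_gain = 12, beta = 100, tau_param = "direct") {
  topology <- match.arg(topology)
  head <- match.arg(head)
  check_that(length(input_shape) == 2 && all(input_shape >= 4),
             "input_shape must be c(H, W) with H, W >= 4")
  pools <- rep_len(pools, length(channels))
  if (is.null(tau_m_base))
    tau_m_base <- if (topology == "feedforward") 4 else 16
  if (is.null(readout_tau))
    readout_tau <- if (head == "tracking") 4 else tau_m_base
  rec <- topology == "recurrent"
  blocks <- lapply(seq_along(channels), function(i)
    block_spec(channels[i], kernel = kernel, pool = pools[i],
               norm = !rec, recurrent = rec))
  # per-block spatial dims
  H <- input_shape[1]; W <- input_shape[2]
  for (i in seq_along(blocks)) {
    check_that(H %/% blocks[[i]]$pool >= 1 && H %% blocks[[i]]$pool == 0 &&
                 W %% blocks[[i]]$pool == 0,
               "pooling must evenly divide the spatial dimensions")
    blocks[[i]]$in_H <- H; blocks[[i]]$in_W <- W
    H <- H %/% blocks[[i]]$pool; W <- W %/% blocks[[i]]$pool
    blocks[[i]]$out_H <- H; blocks[[i]]$out_W <- W
    blocks[[i]]$in_channels <- if (i == 1) 1L else blocks[[i - 1]]$out_channels
  }
  structure(list(topology = topology, input_shape = as.integer(input_shape),
                 blocks = blocks, head = head, n_out = as.integer(n_out),
                 timesteps = as.integer(timesteps),
                 flat_dim = H * W * channels[length(channels)],
                 tau_m_base = tau_m_base, readout_tau = readout_tau,
                 input_gain = input_gain, beta = beta, tau_param = tau_param),
            class = "network_config")
}

#' Build a network in one of the four experimental variants
#'
#' The variants form a 2x2 factorial design: whether weight perturbation is
#' applied during training, and whether the context-modulated adaptation is
#' present. `base` = neither, `perturbed` = perturbation only, `sham` =
#' modulation only, `context` = both. Modulated variants own one trainable
#' projection per output channel of every LIF block.
#'
#' @param config a [network_config()].
#' @param variant one of `"base"`, `"perturbed"`, `"sham"`, `"context"`.
#' @param mod_mode `"threshold"` or `"tau"` for modulated variants; must be
#'   `"none"` for base/perturbed.
#' @param init_seed seed of the weight initialization stream.
#' @param p_init_sd scale of the zero-mean normal projection initializer.
#' @param spike_rate_init assumed input spike rate used to scale the
#'   kernels that consume binary spike trains (every block after the first,
#'   and all recurrent kernels). Dense He-style initialization assumes
#'   unit-variance inputs; binary inputs firing at rate rho have variance
#'   about rho, so those kernels are scaled up by `1/sqrt(rho)` to keep the
#'   initial drive near the firing threshold instead of silencing the
#'   deeper layers.
#' @return object of class `snn_network`. Exposes ideal weights
#'   (`$params`), the perturbable-parameter names (`$perturbable`), the
#'   per-layer modulation projections (`$params[["b<k>.p"]]`), and a state
#'   reset entry point (states are freshly zero-initialized on every
#'   [forward_trial()]).
#' @export
build_network <- function(config,
                          variant = c("base", "perturbed", "sham", "context"),
                          mod_mode = c("none", "threshold", "tau"),
                          init_seed = 1L, p_init_sd = 0.1,
                          spike_rate_init = 0.02) {
  variant <- match.arg(variant)
  mod_mode <- match.arg(mod_mode)
  if (variant %in% c("base", "perturbed"))
    check_that(mod_mode == "none",
               sprintf("variant '%s' has no modulation; mod_mode must be 'none'", variant))
  else
    check_that(mod_mode %in% c("threshold", "tau"),
               sprintf("variant '%s' needs mod_mode 'threshold' or 'tau'", variant))
  params <- list()
  bn <- list()
  perturbable <- character(0)
  with_seed(init_seed, {
    for (i in seq_along(config$blocks)) {
      bl <- config$blocks[[i]]
      nm <- paste0("b", i)
      fan_in <- bl$kernel^2 * bl$in_channels
      sd_in <- sqrt(2 / fan_in) / if (i == 1) 1 else sqrt(spike_rate_init)
      params[[paste0(nm, ".W")]] <-
        array(stats::rnorm(bl$kernel^2 * bl$in_channels * bl$out_channels,
                           sd = sd_in),
              dim = c(bl$kernel, bl$kernel, bl$in_channels, bl$out_channels))
      params[[paste0(nm, ".b")]] <- numeric(bl$out_channels)
      perturbable <- c(perturbable, paste0(nm, ".W"))
      if (bl$recurrent) {
        fr <- bl$kernel^2 * bl$out_channels
        params[[paste0(nm, ".Wrec")]] <-
          array(stats::rnorm(bl$kernel^2 * bl$out_channels^2,
                             sd = sqrt(2 / fr) / sqrt(spike_rate_init)),
                dim = c(bl$kernel, bl$kernel, bl$out_channels, bl$out_channels))
        perturbable <- c(perturbable, paste0(nm, ".Wrec"))
      }
      if (bl$norm) {
        params[[paste0(nm, ".gamma")]] <- rep(1, bl$out_channels)
        params[[paste0(nm, ".beta")]] <- numeric(bl$out_channels)
        bn[[nm]] <- list(mean = numeric(bl$out_channels),
                         var = rep(1, bl$out_channels))
      }
      if (mod_mode != "none")
        params[[paste0(nm, ".p")]] <- init_projection(bl$out_channels, p_init_sd)
    }
    params[["fc.W"]] <- matrix(stats::rnorm(config$flat_dim * config$n_out,
                                            sd = sqrt(1 / config$flat_dim)),
                               config$flat_dim, config$n_out)
    params[["fc.b"]] <- numeric(config$n_out)
    perturbable <- c(perturbable, "fc.W")
  })
  lif <- lif_params(tau_m_base = config$tau_m_base, beta = config$beta,
                    tau_param = config$tau_param)
  structure(list(config = config, variant = variant, mod_mode = mod_mode,
                 params = params, bn = bn, bn_frozen = FALSE,
                 lif = lif, perturbable = perturbable,
                 init_seed = as.integer(init_seed)),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s SNN (%s variant%s): %dx%d input, blocks [%s], %s head (%d out)\n",
              cfg$topology, x$variant,
              if (x$mod_mode != "none") paste0(", ", x$mod_mode, " modulation") else "",
              cfg$input_shape[1], cfg$input_shape[2],
              paste(vapply(cfg$blocks, function(b) b$out_channels, integer(1)),
                    collapse = "/"),
              cfg$head, cfg$n_out))
  cat(sprintf("  tau_m = %g frames, readout tau = %g, %d parameters\n",
              cfg$tau_m_base, cfg$readout_tau, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net an `snn_network`.
#' @return integer count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, integer(1)))

#' @export
coef.snn_network <- function(object, ...) object$params

# --- modulation bookkeeping ----------------------------------------------

# Per-block modulation coefficients for a given context scalar: per-channel
# alpha (= dt / tau_eff), per-channel effective threshold, and the
# derivative d alpha / d p used by the tau-mode backward pass.
block_modulation <- function(net, c) {
  lif <- net$lif
  active <- net$variant %in% c("sham", "context") && net$mod_mode != "none"
  lapply(seq_along(net$config$blocks), function(i) {
    Cout <- net$config$blocks[[i]]$out_channels
    v_th <- rep(lif$v_th_base, Cout)
    tau <- rep(lif$tau_m_base, Cout)
    dalpha_dp <- numeric(Cout)
    if (active) {
      p <- net$params[[paste0("b", i, ".p")]]
      if (net$mod_mode == "threshold") {
        v_th <- effective_threshold(context_mod("threshold", p, c), lif)
      } else {
        tau <- effective_tau(context_mod("tau", p, c), lif)
        if (lif$tau_param == "direct") {
          unclamped <- (lif$tau_m_base + p * c) > lif$tau_min
          dalpha_dp <- ifelse(unclamped, -lif$dt * c / tau^2, 0)
        } else {
          rate <- 1 / lif$tau_m_base + p * c
          unclamped <- rate > 1e-6 & rate < 1 / lif$tau_min
          dalpha_dp <- ifelse(unclamped, lif$dt * c, 0)
        }
      }
    }
    list(alpha = lif$dt / tau, v_th = v_th, dalpha_dp = dalpha_dp)
  })
}

# Expand a per-channel vector to the full (N, H, W, C) element count.
expand_ch <- function(v, nhw) rep(v, each = nhw)

# Per-channel sums of a (N, H, W, C) array.
channel_sums <- function(x, nhw, C) colSums(matrix(x, nhw, C))

# Resolve the effective (possibly perturbed) weights for a forward pass.
# Returns list(w = named list, dw = named list of d w'/d w or NULL).
effective_weights <- function(net, spec, level, phi) {
  w <- net$params
  dw <- NULL
  if (!is.null(phi)) {
    check_that(!is.null(spec), "a perturbation spec is required with a draw")
    dw <- list()
    for (nm in net$perturbable) {
      ap <- apply_perturbation(spec, level, net$params[[nm]], phi[[nm]])
      w[[nm]] <- ap$w
      dw[[nm]] <- ap$dw
    }
  }
  list(w = w, dw = dw)
}

#' Realize the frozen noise tensors of a draw for a network
#'
#' @param net an `snn_network`.
#' @param draw a [perturbation_draw()].
#' @return named list of standard-normal arrays, one per perturbable tensor.
#' @export
network_phi <- function(net, draw) {
  shapes <- lapply(net$params[net$perturbable], function(p)
    if (is.null(dim(p))) length(p) else dim(p))
  draw_phi(draw, shapes)
}

# --- forward pass ---------------------------------------------------------

# Canonicalize input frames to a fetcher closure + (N, T).
frame_source <- function(net, frames) {
  d <- dim(frames)
  g <- net$config$input_gain
  if (length(d) == 3) {          # static (N, H, W): repeat for config$timesteps
    check_that(all(d[2:3] == net$config$input_shape),
               "frame spatial dims do not match the network input shape")
    N <- d[1]; T <- net$config$timesteps
    x <- array(g * frames, c(d, 1L))
    list(N = N, T = T, get = function(t) x, static = TRUE)
  } else if (length(d) == 4) {   # temporal (N, T, H, W)
    check_that(all(d[3:4] == net$config$input_shape),
               "frame spatial dims do not match the network input shape")
    N <- d[1]; T <- d[2]
    list(N = N, T = T,
         get = function(t) array(g * frames[, t, , ], c(N, d[3], d[4], 1L)),
         static = FALSE)
  } else stop("frames must be (N, H, W) or (N, T, H, W)", call. = FALSE)
}

# Core forward pass. Returns readout values per timestep and, when
# train = TRUE, the caches needed by snn_backward(). `bn_env`, when given,
# is an environment holding running batch-norm statistics (mean/var/momentum
# per normalized block) updated in place when bn_training = TRUE.
snn_forward <- function(net, frames, c = 0, spec = NULL, phi = NULL,
                        train = FALSE, bn_training = FALSE, bn_env = NULL,
                        record = FALSE, debug_binary = FALSE) {
  cfg <- net$config
  src <- frame_source(net, frames)
  N <- src$N; T <- src$T
  ew <- effective_weights(net, spec, c, phi)
  w <- ew$w
  mods <- block_modulation(net, c)
  nb <- length(cfg$blocks)
  lif <- net$lif
  # expanded per-element coefficient vectors (constant over the trial)
  alpha_e <- vector("list", nb); vth_e <- vector("list", nb)
  v <- vector("list", nb); zprev <- vector("list", nb)
  for (b in seq_len(nb)) {
    bl <- cfg$blocks[[b]]
    nhw <- N * bl$in_H * bl$in_W
    alpha_e[[b]] <- expand_ch(mods[[b]]$alpha, nhw)
    vth_e[[b]] <- expand_ch(mods[[b]]$v_th, nhw)
    v[[b]] <- array(0, c(N, bl$in_H, bl$in_W, bl$out_channels))
    zprev[[b]] <- array(0, c(N, bl$in_H, bl$in_W, bl$out_channels))
  }
  if (is.null(bn_env)) {
    bn_env <- new.env(parent = emptyenv())
    for (nm in names(net$bn)) {
      e <- new.env(parent = emptyenv())
      e$mean <- net$bn[[nm]]$mean; e$var <- net$bn[[nm]]$var; e$momentum <- 0.1
      assign(nm, e, envir = bn_env)
    }
  }
  a_out <- lif$dt / cfg$readout_tau
  v_out <- matrix(0, N, cfg$n_out)
  outputs <- array(0, c(N, T, cfg$n_out))
  caches <- if (train) vector("list", T) else NULL
  rec_arr <- if (record) {
    bl <- cfg$blocks[[nb]]
    array(0, c(N, T, bl$in_H * bl$in_W * bl$out_channels))
  } else NULL

  static_in <- NULL  # cached first-block conv of a static stimulus
  for (t in seq_len(T)) {
    x <- src$get(t)
    tc <- if (train) vector("list", nb) else NULL
    for (b in seq_len(nb)) {
      bl <- cfg$blocks[[b]]
      nm <- paste0("b", b)
      if (b == 1 && src$static) {
        if (is.null(static_in))
          static_in <- conv_forward(x, w[["b1.W"]], w[["b1.b"]])
        cf <- static_in
      } else {
        cf <- conv_forward(x, w[[paste0(nm, ".W")]], w[[paste0(nm, ".b")]])
      }
      I <- cf$y
      if (bl$recurrent) {
        rf <- conv_forward(zprev[[b]], w[[paste0(nm, ".Wrec")]],
                           numeric(bl$out_channels))
        I <- I + rf$y
      }
      bnc <- NULL
      if (bl$norm) {
        bf <- bn_forward(I, w[[paste0(nm, ".gamma")]], w[[paste0(nm, ".beta")]],
                         get(nm, envir = bn_env),
                         training = bn_training && !net$bn_frozen)
        I <- bf$y
        bnc <- bf[c("xhat", "istd", "training")]
      }
      if (!is.finite(sum(I)))
        stop(sprintf("non-finite activation at timestep %d, block %d", t, b),
             call. = FALSE)
      vpre <- v[[b]] + alpha_e[[b]] * (lif$v_leak - v[[b]] + I)
      z <- (as.numeric(vpre) > vth_e[[b]]) + 0
      dim(z) <- dim(vpre)
      v[[b]] <- (1 - z) * vpre + z * lif$v_reset
      if (record && b == nb) rec_arr[, t, ] <- matrix(vpre, N)
      pf <- pool_forward(z, bl$pool)
      if (debug_binary)
        check_that(all(pf$y %in% c(0, 1)),
                   "inter-block tensor is not binary")
      if (train)
        tc[[b]] <- list(vpre = vpre, z = z, amax = pf$amax, in_len = pf$in_len,
                        pooled = pf$y, bnc = bnc, xin = if (b == 1) NULL else x)
      zprev[[b]] <- z
      x <- pf$y
    }
    flat <- matrix(x, N, cfg$flat_dim)
    pre <- flat %*% w[["fc.W"]] + rep(w[["fc.b"]], each = N)
    v_out <- v_out + a_out * (lif$v_leak - v_out + pre)
    outputs[, t, ] <- v_out
    if (train) caches[[t]] <- list(blocks = tc, flat = flat)
  }
  list(outputs = outputs, N = N, T = T, caches = caches, w = w, dw = ew$dw,
       mods = mods, alpha_e = alpha_e, vth_e = vth_e, a_out = a_out,
       record = rec_arr, src = src, bn_env = bn_env, context_c = c)
}

# BPTT backward pass. `d_out` is dL/d outputs, an (N, T, n_out) array (zeros
# where the loss does not read the output). Returns named gradients for the
# ideal parameters (perturbation chain rule applied).
snn_backward <- function(net, fw, d_out, train_p = TRUE) {
  cfg <- net$config
  nb <- length(cfg$blocks)
  lif <- net$lif
  N <- fw$N; T <- fw$T
  w <- fw$w
  grads <- lapply(net$params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  d_vout <- matrix(0, N, cfg$n_out)
  d_vcarry <- vector("list", nb)
  d_zrec <- vector("list", nb)
  for (b in seq_len(nb)) {
    bl <- cfg$blocks[[b]]
    d_vcarry[[b]] <- array(0, c(N, bl$in_H, bl$in_W, bl$out_channels))
  }
  mod_active <- net$variant %in% c("sham", "context") && net$mod_mode != "none"
  ctx <- NULL
  for (t in seq(T, 1)) {
    ca <- fw$caches[[t]]
    d_vout <- d_vout + matrix(d_out[, t, ], N, cfg$n_out)
    d_fcpre <- fw$a_out * d_vout
    grads[["fc.W"]] <- grads[["fc.W"]] + crossprod(ca$flat, d_fcpre)
    grads[["fc.b"]] <- grads[["fc.b"]] + colSums(d_fcpre)
    d_pooled_next <- d_fcpre %*% t(w[["fc.W"]])
    bl_last <- cfg$blocks[[nb]]
    dim(d_pooled_next) <- c(N, bl_last$out_H, bl_last$out_W, bl_last$out_channels)
    d_vout <- (1 - fw$a_out) * d_vout
    for (b in seq(nb, 1)) {
      bl <- cfg$blocks[[b]]
      nm <- paste0("b", b)
      cb <- ca$blocks[[b]]
      nhw <- N * bl$in_H * bl$in_W
      # gradient into this block's spikes: from pooling (downstream) and
      # from the recurrent convolution at t + 1
      dz <- pool_backward(d_pooled_next, cb$amax, cb$in_len)
      dim(dz) <- c(N, bl$in_H, bl$in_W, bl$out_channels)
      if (!is.null(d_zrec[[b]])) dz <- dz + d_zrec[[b]]
      sg <- surrogate_grad(as.numeric(cb$vpre), fw$vth_e[[b]], lif$beta)
      dzsg <- as.numeric(dz) * sg
      d_vpre <- dzsg + as.numeric(d_vcarry[[b]]) * (1 - as.numeric(cb$z))
      if (mod_active && train_p) {
        if (net$mod_mode == "threshold") {
          # z depends on v_th through the jump condition; d v_th/d p = c
          gp <- -channel_sums(dzsg, nhw, bl$out_channels) * ctx_c(fw)
          grads[[paste0(nm, ".p")]] <- grads[[paste0(nm, ".p")]] + gp
        } else {
          vprev <- if (t > 1) {
            pz <- fw$caches[[t - 1]]$blocks[[b]]
            (1 - pz$z) * pz$vpre + pz$z * lif$v_reset
          } else array(0, dim(cb$vpre))
          # v' = v + alpha (v_leak - v + I): recover the drive term from the
          # cached pre/post potentials
          drive <- (as.numeric(cb$vpre) - as.numeric(vprev)) / fw$alpha_e[[b]]
          d_alpha <- d_vpre * drive
          gp <- channel_sums(d_alpha, nhw, bl$out_channels) * fw$mods[[b]]$dalpha_dp
          grads[[paste0(nm, ".p")]] <- grads[[paste0(nm, ".p")]] + gp
        }
      }
      d_vcarry[[b]] <- d_vpre * (1 - fw$alpha_e[[b]])
      dim(d_vcarry[[b]]) <- dim(cb$vpre)
      d_I <- d_vpre * fw$alpha_e[[b]]
      dim(d_I) <- dim(cb$vpre)
      if (bl$norm) {
        bb <- bn_backward(d_I, cb$bnc, w[[paste0(nm, ".gamma")]])
        grads[[paste0(nm, ".gamma")]] <- grads[[paste0(nm, ".gamma")]] + bb$ggamma
        grads[[paste0(nm, ".beta")]] <- grads[[paste0(nm, ".beta")]] + bb$gbeta
        d_conv <- bb$dx
      } else d_conv <- d_I
      xin <- if (b == 1) fw$src$get(t) else cb$xin
      cbk <- conv_backward(d_conv, xin, w[[paste0(nm, ".W")]],
                           need_dx = (b > 1))
      grads[[paste0(nm, ".W")]] <- grads[[paste0(nm, ".W")]] + cbk$gW
      grads[[paste0(nm, ".b")]] <- grads[[paste0(nm, ".b")]] + cbk$gb
      if (b > 1) d_pooled_next <- cbk$dx
      if (bl$recurrent) {
        zp <- if (t > 1) fw$caches[[t - 1]]$blocks[[b]]$z
              else array(0, dim(cb$z))
        rbk <- conv_backward(d_conv, zp, w[[paste0(nm, ".Wrec")]],
                             need_dx = (t > 1))
        grads[[paste0(nm, ".Wrec")]] <- grads[[paste0(nm, ".Wrec")]] + rbk$gW
        d_zrec[b] <- list(if (t > 1) rbk$dx else NULL)
      }
    }
  }
  # route gradients of perturbed tensors back to the ideal weights
  if (!is.null(fw$dw))
    for (nm in names(fw$dw))
      grads[[nm]] <- grads[[nm]] * fw$dw[[nm]]
  for (nm in names(grads))
    if (is.null(dim(net$params[[nm]]))) grads[[nm]] <- as.numeric(grads[[nm]])
  grads
}

# context scalar used in the forward pass (needed for threshold-mode p grads)
ctx_c <- function(fw) fw$context_c

#' Run one trial through a network
#'
#' States are zero-initialized at trial start (the state-reset entry point),
#' the perturbation (if any) is realized once from the draw and frozen over
#' all timesteps, and the context scalar is fed to the modulated layers of
#' sham/context variants. Classification heads return the leaky-integrator
#' logits at the final timestep; tracking heads return the readout at every
#' timestep.
#'
#' @param net an `snn_network`.
#' @param frames `(N, H, W)` static frames (presented for
#'   `config$timesteps`) or `(N, T, H, W)` temporal frames.
#' @param c context scalar / perturbation level in `[0, 1]`.
#' @param spec perturbation model ([gaussian_spec()] or [dose_spec()]);
#'   required when `draw` is given.
#' @param draw a [perturbation_draw()], or `NULL` for ideal weights.
#' @param all_timesteps logical; classification heads may return the full
#'   readout timecourse instead of the final-step logits.
#' @param record logical; also return the pre-threshold membrane potentials
#'   of the penultimate activation layer (trials x timesteps x units).
#' @param debug_binary logical; assert at runtime that every inter-block
#'   tensor is binary.
#' @return for classification, an `(N, n_classes)` logits matrix (or the
#'   full `(N, T, n_classes)` array when `all_timesteps = TRUE`); for
#'   tracking, an `(N, T, 2)` readout array in normalized coordinates. When
#'   `record = TRUE`, a list with elements `out` and `potentials`.
#' @export
forward_trial <- function(net, frames, c = 0, spec = gaussian_spec(),
                          draw = NULL, all_timesteps = FALSE,
                          record = FALSE, debug_binary = FALSE) {
  check_that(all(is.finite(frames)), "frames must be finite")
  phi <- if (is.null(draw)) NULL else network_phi(net, draw)
  if (!is.null(draw) && isTRUE(draw$per_sample)) {
    d <- dim(frames)
    outs <- lapply(seq_len(d[1]), function(i) {
      fi <- if (length(d) == 3) frames[i, , , drop = FALSE]
            else frames[i, , , , drop = FALSE]
      forward_trial(net, fi, c = c, spec = spec,
                    draw = perturbation_draw(draw$seed + i),
                    all_timesteps = all_timesteps, record = record,
                    debug_binary = debug_binary)
    })
    return(combine_trial_outputs(outs, record))
  }
  fw <- snn_forward(net, frames, c = c, spec = spec, phi = phi,
                    record = record, debug_binary = debug_binary)
  out <- if (net$config$head == "classification" && !all_timesteps)
    matrix(fw$outputs[, fw$T, ], fw$N, net$config$n_out)
  else fw$outputs
  if (record) list(out = out, potentials = fw$record) else out
}

combine_trial_outputs <- function(outs, record) {
  pick <- function(o) if (record) o$out else o
  first <- pick(outs[[1]])
  if (is.matrix(first)) {
    out <- do.call(rbind, lapply(outs, pick))
  } else {
    dims <- dim(first); dims[1] <- length(outs)
    out <- array(0, dims)
    for (i in seq_along(outs)) out[i, , ] <- pick(outs[[i]])
  }
  if (record) {
    dims <- dim(outs[[1]]$potentials); dims[1] <- length(outs)
    pot <- array(0, dims)
    for (i in seq_along(outs)) pot[i, , ] <- outs[[i]]$potentials
    list(out = out, potentials = pot)
  } else out
}

#' @export
predict.snn_network <- function(object, frames, c = 0, spec = gaussian_spec(),
                                draw = NULL, ...) {
  out <- forward_trial(object, frames, c = c, spec = spec, draw = draw)
  if (object$config$head == "classification") {
    cls <- max.col(out, ties.method = "first")
    structure(cls, logits = out)
  } else out
}
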