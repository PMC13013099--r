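#' Default experiment configuration
#'
#' The full, nested configuration driving [run_experiment()]. Two presets
#' exist: `"tiny"` is the desk-scale setup every test and example runs
#' (16x16 small-object tracking over 50 frames, a 3-block network with
#' 4/8/16 channels, 3 seeds, reduced epochs); `"paper"` scales the same
#' pipeline up (larger frames, 8/16/32-channel blocks at the small end of
#' the full-scale design, 100-epoch phases, 10 seeds, the full 10-level
#' grid) and is a documented flag rather than the test path.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @return nested named list of settings.
#' @export
default_config <- function(preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1L,
    preset = preset,
    task = list(type = "sot", height = 16L, width = 16L, timesteps = 50L,
                n_train = 48L, n_test = 16L, speed = 0.2, contrast = 2,
                clutter_amplitude = 0.2, noise_sigma = 0.05, jitter_sd = 0.05,
                n_classes = 5L),
    network = list(topology = "recurrent", channels = c(4L, 8L, 16L),
                   pools = c(2L, 2L, 1L), kernel = 3L,
                   tau_m_base = NULL, readout_tau = NULL, input_gain = 12,
                   beta = 10, tau_param = "direct", spike_rate_init = 0.005),
    perturbation = list(model = "gaussian", table = NULL),
    training = list(epochs_pretrain = 30L, epochs_adapt = 30L,
                    lr_pretrain = 0.1, lr_adapt = 0.02, momentum = 0.9,
                    batch_size = 8L, patience = 10L, lr_factor = 0.5,
                    clip_pretrain = 5, clip_adapt = 2,
                    context_sampling = "uniform",
                    p_lr_scale_threshold = 25, p_lr_scale_tau = 6000),
    sweep = list(variants = c("perturbed", "context"),
                 mod_modes = c("threshold", "tau"),
                 c_max = 1.0, test_levels = c(0, 1.0),
                 seeds = c(1L, 2L, 3L), n_draws = 5L),
    latent = list(enabled = TRUE, contexts = c(0, 0.2, 1.0))
  )
  if (preset == "paper") {
    cfg$task$height <- 32L; cfg$task$width <- 32L
    cfg$task$timesteps <- 100L
    cfg$task$n_train <- 2048L; cfg$task$n_test <- 512L
    cfg$network$channels <- c(8L, 16L, 32L)
    cfg$network$pools <- c(2L, 2L, 2L)
    cfg$network$beta <- 100
    cfg$training$epochs_pretrain <- 100L; cfg$training$epochs_adapt <- 100L
    cfg$training$lr_pretrain <- 0.001; cfg$training$lr_adapt <- 0.001
    cfg$training$batch_size <- 64L
    cfg$sweep$c_max <- seq(0.1, 1, length.out = 10)
    cfg$sweep$test_levels <- seq(0, 1, length.out = 10)
    cfg$sweep$seeds <- 1:10
  }
  cfg
}

#' Load and validate an experiment configuration (YAML)
#'
#' Unknown keys anywhere in the tree are rejected by name; missing keys are
#' filled from the preset defaults. `save_config()` writes a configuration
#' back to YAML; a save/load round trip is idempotent.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  check_that(file.exists(path), paste("no such config file:", path))
  user <- yaml::read_yaml(path)
  preset <- if (!is.null(user$preset)) user$preset else "tiny"
  check_that(preset %in% c("tiny", "paper"), "preset must be 'tiny' or 'paper'")
  defaults <- default_config(preset)
  merge_config(defaults, user, path = "")
}

merge_config <- function(defaults, user, path) {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  check_that(length(extra) == 0,
             sprintf("unknown config key%s: %s",
                     if (length(extra) > 1) "s" else "",
                     paste0(sub("^\\.", "", paste0(path, ".", extra)),
                            collapse = ", ")))
  out <- defaults
  for (nm in names(user)) {
    val <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]], paste0(path, ".", nm))
    else user[[nm]]
    out[nm] <- list(val)   # keeps explicit NULLs instead of dropping the key
  }
  out
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Materialize the R objects described by a configuration.
config_objects <- function(config, seed = config$seed) {
  ss <- seed_streams(seed)
  tk <- config$task
  nw <- config$network
  if (tk$type == "sot") {
    mk <- function(s, n) generate_sot(
      sot_config(height = tk$height, width = tk$width, timesteps = tk$timesteps,
                 contrast = tk$contrast, clutter_amplitude = tk$clutter_amplitude,
                 noise_sigma = tk$noise_sigma, speed = tk$speed,
                 jitter_sd = tk$jitter_sd, seed = s), n)
    head <- "tracking"; n_out <- 2L
  } else {
    mk <- function(s, n) generate_toy_classification(
      toyclass_config(n_classes = tk$n_classes, height = tk$height,
                      width = tk$width, noise_sigma = tk$noise_sigma,
                      timesteps = tk$timesteps, seed = s,
                      template_seed = ss$data), n)
    head <- "classification"; n_out <- tk$n_classes
  }
  ncfg <- network_config(nw$topology, c(tk$height, tk$width),
                         channels = nw$channels, pools = nw$pools,
                         kernel = nw$kernel, head = head, n_out = n_out,
                         timesteps = tk$timesteps, tau_m_base = nw$tau_m_base,
                         readout_tau = nw$readout_tau,
                         input_gain = nw$input_gain, beta = nw$beta,
                         tau_param = nw$tau_param)
  spec <- if (config$perturbation$model == "gaussian") gaussian_spec()
          else dose_spec(if (is.null(config$perturbation$table)) NULL
                         else dose_table_load(config$perturbation$table))
  list(streams = ss, make_data = mk, net_config = ncfg, spec = spec,
       head = head)
}

#' Train all variants of the recovery experiment and evaluate the sweep
#'
#' The core experimental pipeline: generate train/hold-out data, pretrain a
#' base model per seed, adapt-train each configured (variant, modulation)
#' combination to each training maximum, and evaluate everything on the
#' hold-out set at every test level. Returns the trained fits and the
#' metric grid; [run_experiment()] wraps this with on-disk artifacts.
#'
#' @param config configuration list (see [default_config()]).
#' @param verbose print per-epoch training progress.
#' @return list with `fits` (named by [grid_key()]), `pretrained` (per
#'   seed), `grid` (a `sweep_grid`), `train`, `test` (datasets) and `spec`.
#' @export
run_recovery <- function(config = default_config("tiny"), verbose = FALSE) {
  ob <- config_objects(config)
  tr <- ob$make_data(ob$streams$data, config$task$n_train)
  te <- ob$make_data(ob$streams$data + 1L, config$task$n_test)
  tc <- config$training
  sw <- config$sweep
  fits <- list()
  pres <- list()
  for (s in sw$seeds) {
    net <- build_network(ob$net_config, "base",
                         init_seed = ob$streams$init + s,
                         spike_rate_init = config$network$spike_rate_init)
    pre <- pretrain(net, tr, train_config(
      epochs = tc$epochs_pretrain, lr = tc$lr_pretrain,
      momentum = tc$momentum, patience = tc$patience,
      lr_factor = tc$lr_factor, batch_size = tc$batch_size,
      clip = tc$clip_pretrain, seed = ob$streams$init + 1000L * s,
      verbose = verbose))
    pres[[as.character(s)]] <- pre
    for (v in sw$variants) {
      mods <- if (v == "perturbed") "none" else sw$mod_modes
      for (mm in mods) {
        for (cm in sw$c_max) {
          psc <- switch(mm, threshold = tc$p_lr_scale_threshold,
                        tau = tc$p_lr_scale_tau, 1)
          fit <- adapt_train(pre, v, mm, c_max = cm, tr, train_config(
            epochs = tc$epochs_adapt, lr = tc$lr_adapt,
            momentum = tc$momentum, patience = tc$patience,
            lr_factor = tc$lr_factor, batch_size = tc$batch_size,
            context_sampling = tc$context_sampling, p_lr_scale = psc,
            clip = tc$clip_adapt,
            seed = ob$streams$init + 1000L * s + 7L,
            verbose = verbose), spec = ob$spec,
            init_seed = ob$streams$init + 500L * s)
          fits[[grid_key(v, mm, cm, s)]] <- fit
        }
      }
    }
  }
  grid <- run_grid(fits, te, sw$test_levels, spec = ob$spec,
                   n_draws = sw$n_draws,
                   batch_size = min(16L, config$task$n_test))
  list(fits = fits, pretrained = pres, grid = grid, train = tr, test = te,
       spec = ob$spec, config = config)
}

#' Run a full experiment with on-disk artifacts
#'
#' Orchestrates the stages generate, pretrain, adapt, sweep and latent under
#' an output directory. Each stage writes its artifacts plus a done-marker
#' and is skipped on re-run when the marker exists, so a completed
#' experiment re-runs as a no-op and an interrupted one resumes. A manifest
#' (JSON) in the output directory records the configuration snapshot, seed
#' streams, package version, artifact paths, and per-stage status.
#'
#' @param config configuration list, see [default_config()] / [load_config()].
#' @param out_dir output directory (created if missing).
#' @param dry_run if `TRUE`, print the execution plan and run nothing.
#' @param verbose print training progress.
#' @return invisibly, the manifest list.
#' @export
run_experiment <- function(config = default_config("tiny"), out_dir,
                           dry_run = FALSE, verbose = FALSE) {
  sw <- config$sweep
  plan <- c("generate: train/test datasets",
            sprintf("pretrain: base model x %d seeds", length(sw$seeds)),
            sprintf("adapt: %s x c_max {%s} x %d seeds",
                    paste(sw$variants, collapse = "/"),
                    paste(sw$c_max, collapse = ","), length(sw$seeds)),
            sprintf("sweep: test levels {%s}, %d draws/cell",
                    paste(sw$test_levels, collapse = ","), sw$n_draws),
            if (isTRUE(config$latent$enabled)) "latent: trajectory records + embeddings")
  if (dry_run) {
    cat("experiment plan:\n")
    for (p in plan) cat(" -", p, "\n")
    return(invisible(list(plan = plan, executed = FALSE)))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- function(stage) file.path(out_dir, paste0(".done_", stage))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(config = config, seeds = seed_streams(config$seed),
                   package_version = as.character(utils::packageVersion("contextsnn")),
                   stages = list(), artifacts = list())
  note <- function(stage, status, paths = NULL) {
    manifest$stages[[stage]] <<- status
    if (!is.null(paths)) manifest$artifacts[[stage]] <<- paths
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  ob <- config_objects(config)

  # generate
  tr_path <- file.path(out_dir, "train.rds"); te_path <- file.path(out_dir, "test.rds")
  if (!file.exists(marker("generate"))) {
    tr <- ob$make_data(ob$streams$data, config$task$n_train)
    te <- ob$make_data(ob$streams$data + 1L, config$task$n_test)
    save_dataset(tr, tr_path); save_dataset(te, te_path)
    file.create(marker("generate"))
    note("generate", "done", c(tr_path, te_path))
  } else {
    tr <- load_dataset(tr_path); te <- load_dataset(te_path)
    note("generate", "cached")
  }

  tc <- config$training
  # pretrain
  pres <- list()
  for (s in sw$seeds) {
    ck <- file.path(out_dir, sprintf("pretrain_seed%d.rds", s))
    if (file.exists(ck)) { pres[[as.character(s)]] <- load_checkpoint(ck); next }
    net <- build_network(ob$net_config, "base", init_seed = ob$streams$init + s,
                         spike_rate_init = config$network$spike_rate_init)
    pre <- pretrain(net, tr, train_config(
      epochs = tc$epochs_pretrain, lr = tc$lr_pretrain, momentum = tc$momentum,
      patience = tc$patience, lr_factor = tc$lr_factor,
      batch_size = tc$batch_size, clip = tc$clip_pretrain,
      seed = ob$streams$init + 1000L * s, verbose = verbose))
    save_checkpoint(pre, ck)
    pres[[as.character(s)]] <- pre
  }
  note("pretrain", "done")

  # adapt
  fits <- list()
  for (s in sw$seeds) for (v in sw$variants) {
    mods <- if (v %in% c("base", "perturbed")) "none" else sw$mod_modes
    for (mm in mods) for (cm in sw$c_max) {
      key <- grid_key(v, mm, cm, s)
      ck <- file.path(out_dir, sprintf("adapt_%s.rds",
                                       gsub("[^A-Za-z0-9._-]", "_", key)))
      if (file.exists(ck)) { fits[[key]] <- load_checkpoint(ck); next }
      psc <- switch(mm, threshold = tc$p_lr_scale_threshold,
                    tau = tc$p_lr_scale_tau, 1)
      fit <- adapt_train(pres[[as.character(s)]], v, mm, c_max = cm, tr,
                         train_config(epochs = tc$epochs_adapt, lr = tc$lr_adapt,
                                      momentum = tc$momentum, patience = tc$patience,
                                      lr_factor = tc$lr_factor,
                                      batch_size = tc$batch_size,
                                      context_sampling = tc$context_sampling,
                                      p_lr_scale = psc, clip = tc$clip_adapt,
                                      seed = ob$streams$init + 1000L * s + 7L,
                                      verbose = verbose),
                         spec = ob$spec, init_seed = ob$streams$init + 500L * s)
      save_checkpoint(fit, ck)
      fits[[key]] <- fit
    }
  }
  note("adapt", "done")

  # sweep
  grid_path <- file.path(out_dir, "grid.csv")
  if (!file.exists(marker("sweep"))) {
    grid <- run_grid(fits, te, sw$test_levels, spec = ob$spec,
                     n_draws = sw$n_draws,
                     cache_dir = file.path(out_dir, "cells"),
                     batch_size = min(16L, config$task$n_test))
    write_grid(grid, grid_path)
    file.create(marker("sweep"))
    note("sweep", "done", grid_path)
  } else note("sweep", "cached", grid_path)

  # latent
  if (isTRUE(config$latent$enabled)) {
    traj_path <- file.path(out_dir, "trajectories.rds")
    sep_path <- file.path(out_dir, "separation.csv")
    if (!file.exists(marker("latent"))) {
      recs <- lapply(fits, function(f)
        record_trajectories(f, te, contexts = config$latent$contexts,
                            spec = ob$spec,
                            draw_seed = ob$streams$perturb))
      save_trajectories(recs, traj_path)
      if (te$task == "toyclass") {
        sep <- do.call(rbind, lapply(names(recs), function(k) {
          do.call(rbind, lapply(recs[[k]], function(r) {
            emb <- pca_trajectories(r, 2)
            data.frame(key = k, context = r$context,
                       separation = class_separation(emb))
          }))
        }))
        utils::write.csv(sep, sep_path, row.names = FALSE)
      }
      file.create(marker("latent"))
      note("latent", "done", traj_path)
    } else note("latent", "cached", traj_path)
  }
  invisible(manifest)
}
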