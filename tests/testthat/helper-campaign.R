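# Memoized desk-scale training campaigns shared by the acceptance tests.
# Each campaign is computed once per test session and reused.

.campaign_cache <- new.env(parent = emptyenv())

memoize <- function(key, fn) {
  if (is.null(.campaign_cache[[key]])) .campaign_cache[[key]] <- fn()
  .campaign_cache[[key]]
}

# The tiny small-object-tracking recovery experiment: 16x16 frames, 50
# timesteps, 3-block network, 3 seeds, perturbed vs context (both modulation
# modes), trained to c_max = 1 and evaluated at levels 0 and 1.
sot_campaign <- function(topology) {
  memoize(paste0("sot_", topology), function() {
    cfg <- default_config("tiny")
    cfg$network$topology <- topology
    run_recovery(cfg)
  })
}

# Tiny recurrent toy-classification campaign used for the latent-trajectory
# analysis (class labels are needed for the separation score).
toyclass_campaign <- function() {
  memoize("toyclass_rec", function() {
    cfg <- default_config("tiny")
    cfg$task <- list(type = "toyclass", height = 8L, width = 8L,
                     timesteps = 16L, n_train = 60L, n_test = 30L,
                     speed = 0, contrast = 2, clutter_amplitude = 0,
                     noise_sigma = 0.1, jitter_sd = 0, n_classes = 5L)
    cfg$network$channels <- c(4L, 8L)
    cfg$network$pools <- c(2L, 1L)
    cfg$training$epochs_pretrain <- 20L
    cfg$training$epochs_adapt <- 20L
    cfg$training$lr_pretrain <- 0.05
    cfg$training$batch_size <- 10L
    cfg$sweep$mod_modes <- "threshold"
    res <- run_recovery(cfg)
    # separation scores at the highest level; each record realizes an
    # independent frozen draw per trial, and three record repetitions are
    # averaged to reduce draw noise further
    sep <- list()
    for (key in names(res$fits)) {
      sep[[key]] <- mean(vapply(1:3, function(d) {
        rec <- record_trajectories(res$fits[[key]], res$test, contexts = 1,
                                   spec = res$spec, draw_seed = 1230 + 7 * d)
        class_separation(pca_trajectories(rec[[1]], 2))
      }, numeric(1)))
    }
    res$separation <- sep
    res
  })
}

# Seed-averaged cell means of a recovery grid, keyed by variant/mod/level.
campaign_means <- function(res) {
  cells <- grid_cells(res$grid, over = "seeds")
  setNames(cells$metric,
           paste(cells$variant, cells$mod, cells$test_level, sep = "|"))
}
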