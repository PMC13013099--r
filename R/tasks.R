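#' Small-object-tracking (SOT) task configuration
#'
#' Emulates a remote-sensing-style video: a single bright pixel moving over a
#' cluttered background for `timesteps` frames, with per-timestep (x, y)
#' regression targets. Motion is constant velocity plus Gaussian positional
#' jitter with reflective boundaries, so the object always stays in frame.
#' Coordinates are (x, y) = (column, row), zero-based; the track is
#' continuous and only rounded for rendering.
#'
#' @param height,width frame size in pixels.
#' @param timesteps frames per video (default 100).
#' @param contrast object intensity added on top of the background (> 0).
#' @param clutter_amplitude amplitude of the static smooth background clutter.
#' @param noise_sigma standard deviation of the per-frame pixel noise.
#' @param speed object speed in pixels per frame.
#' @param jitter_sd standard deviation of the per-step positional jitter.
#' @param seed generation seed.
#' @return object of class `sot_config`.
#' @export
sot_config <- function(height = 16, width = 16, timesteps = 100,
                       contrast = 2, clutter_amplitude = 0.2,
                       noise_sigma = 0.05, speed = 0.3, jitter_sd = 0.05,
                       seed = 1) {
  check_that(timesteps >= 2, "timesteps must be >= 2")
  check_that(contrast > 0, "contrast must be > 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 timesteps = as.integer(timesteps), contrast = contrast,
                 clutter_amplitude = clutter_amplitude,
                 noise_sigma = noise_sigma, speed = speed,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "sot_config")
}

# Smooth random field: coarse white noise bilinearly upsampled.
smooth_field <- function(h, w, coarse = 4) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  ys <- seq(1, coarse, length.out = h)
  xs <- seq(1, coarse, length.out = w)
  y0 <- pmin(floor(ys), coarse - 1); x0 <- pmin(floor(xs), coarse - 1)
  ty <- ys - y0; tx <- xs - x0
  out <- matrix(0, h, w)
  for (j in seq_len(w)) {
    c0 <- g[, x0[j]] * (1 - tx[j]) + g[, x0[j] + 1] * tx[j]
    out[, j] <- c0[y0] * (1 - ty) + c0[y0 + 1] * ty
  }
  out
}

#' Generate small-object-tracking videos
#'
#' @param config a [sot_config()].
#' @param n_samples number of videos.
#' @param initial_position optional `c(x, y)` start (must be in frame);
#'   default uniform random.
#' @return object of class `sot_data`: list with `frames`
#'   `(n, T, H, W)`, `tracks` `(n, T, 2)` continuous zero-based (x, y)
#'   coordinates, and the generating `config` (regeneration is bit-exact).
#' @export
generate_sot <- function(config, n_samples, initial_position = NULL) {
  H <- config$height; W <- config$width; T <- config$timesteps
  if (!is.null(initial_position))
    check_that(initial_position[1] >= 0 && initial_position[1] <= W - 1 &&
                 initial_position[2] >= 0 && initial_position[2] <= H - 1,
               "initial object position out of bounds")
  frames <- array(0, c(n_samples, T, H, W))
  tracks <- array(0, c(n_samples, T, 2))
  with_seed(config$seed, {
    for (i in seq_len(n_samples)) {
      bg <- config$clutter_amplitude * smooth_field(H, W)
      pos <- if (is.null(initial_position))
        c(stats::runif(1, 0, W - 1), stats::runif(1, 0, H - 1))
      else as.numeric(initial_position)
      ang <- stats::runif(1, 0, 2 * pi)
      vel <- config$speed * c(cos(ang), sin(ang))
      for (t in seq_len(T)) {
        tracks[i, t, ] <- pos
        fr <- bg + matrix(stats::rnorm(H * W, sd = config$noise_sigma), H, W)
        row <- round(pos[2]) + 1L; col <- round(pos[1]) + 1L
        fr[row, col] <- fr[row, col] + config$contrast
        frames[i, t, , ] <- fr
        # advance: constant velocity + jitter, reflective walls
        pos <- pos + vel + stats::rnorm(2, sd = config$jitter_sd)
        for (k in 1:2) {
          lim <- c(W - 1, H - 1)[k]
          if (pos[k] < 0) { pos[k] <- -pos[k]; vel[k] <- -vel[k] }
          if (pos[k] > lim) { pos[k] <- 2 * lim - pos[k]; vel[k] <- -vel[k] }
          pos[k] <- min(max(pos[k], 0), lim)
        }
      }
    }
  })
  structure(list(frames = frames, tracks = tracks, config = config,
                 task = "sot", seed = config$seed),
            class = c("sot_data", "snn_data"))
}

#' Toy frame-classification task configuration
#'
#' A procedurally generated stand-in for a static image-classification
#' dataset so the classification pipeline runs without downloads: each class
#' owns a distinct smooth random template, and samples are the class template
#' plus pixel noise, presented for `timesteps` frames. An ideal
#' (nearest-template) observer reaches 100% accuracy at zero noise.
#'
#' @param n_classes number of classes (>= 2).
#' @param height,width frame size.
#' @param noise_sigma per-sample pixel noise.
#' @param timesteps presentation length (default 32).
#' @param contrast template scale.
#' @param seed sample-generation seed (noise and label order).
#' @param template_seed seed fixing the class templates; kept separate from
#'   `seed` so train and hold-out sets drawn with different sample seeds
#'   share the same classes.
#' @return object of class `toyclass_config`.
#' @export
toyclass_config <- function(n_classes = 5, height = 16, width = 16,
                            noise_sigma = 0.1, timesteps = 32,
                            contrast = 1, seed = 1, template_seed = 1000) {
  check_that(n_classes >= 2, "need at least 2 classes")
  structure(list(n_classes = as.integer(n_classes),
                 height = as.integer(height), width = as.integer(width),
                 noise_sigma = noise_sigma, timesteps = as.integer(timesteps),
                 contrast = contrast, seed = as.integer(seed),
                 template_seed = as.integer(template_seed)),
            class = "toyclass_config")
}

#' Generate toy classification frames
#'
#' Class-balanced and seeded; two generations with the same config are
#' identical.
#'
#' @param config a [toyclass_config()].
#' @param n_samples number of frames.
#' @return object of class `toyclass_data`: list with `frames` `(n, H, W)`,
#'   integer `labels` in `1..n_classes`, the class `templates`
#'   `(K, H, W)`, and the generating `config`.
#' @export
generate_toy_classification <- function(config, n_samples) {
  K <- config$n_classes; H <- config$height; W <- config$width
  frames <- array(0, c(n_samples, H, W))
  templates <- array(0, c(K, H, W))
  with_seed(config$template_seed, {
    for (k in seq_len(K)) {
      f <- smooth_field(H, W, coarse = 4)
      templates[k, , ] <- config$contrast * (f - mean(f)) / stats::sd(f)
    }
  })
  with_seed(config$seed, {
    labels <- rep_len(seq_len(K), n_samples)[sample.int(n_samples)]
    for (i in seq_len(n_samples))
      frames[i, , ] <- templates[labels[i], , ] +
        matrix(stats::rnorm(H * W, sd = config$noise_sigma), H, W)
  })
  structure(list(frames = frames, labels = labels, templates = templates,
                 config = config, task = "toyclass", seed = config$seed),
            class = c("toyclass_data", "snn_data"))
}

#' Number of samples in a dataset
#' @param data an `snn_data` object.
#' @return integer.
#' @export
n_samples <- function(data) dim(data$frames)[1]

#' Subset a dataset by sample index
#' @param data an `snn_data` object.
#' @param idx integer sample indices.
#' @return dataset of the same class restricted to `idx`.
#' @export
data_subset <- function(data, idx) {
  out <- data
  if (data$task == "sot") {
    out$frames <- data$frames[idx, , , , drop = FALSE]
    out$tracks <- data$tracks[idx, , , drop = FALSE]
  } else {
    out$frames <- data$frames[idx, , , drop = FALSE]
    out$labels <- data$labels[idx]
  }
  out
}

#' Nearest-template classification accuracy (ideal observer)
#'
#' Independent reference classifier for the toy task: assigns each frame to
#' the class whose template is nearest in Euclidean distance.
#'
#' @param data a `toyclass_data`.
#' @return accuracy in `[0, 1]`.
#' @export
template_match_accuracy <- function(data) {
  n <- n_samples(data)
  K <- data$config$n_classes
  tm <- matrix(data$templates, K)
  fm <- matrix(data$frames, n)
  d2 <- outer(rowSums(fm^2), rowSums(tm^2), "+") - 2 * fm %*% t(tm)
  mean(max.col(-d2, ties.method = "first") == data$labels)
}

#' Persist / restore a dataset with its provenance
#'
#' Datasets are stored as a single serialized object carrying the frames,
#' targets, generating config and seed, so regeneration and reloads are
#' bit-exact.
#'
#' @param data an `snn_data` object.
#' @param path file path (`.rds`).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   restored object.
#' @export
save_dataset <- function(data, path) {
  saveRDS(data, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
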