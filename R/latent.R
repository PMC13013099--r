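#' Record penultimate-layer membrane trajectories
#'
#' Runs inference on a set of samples at each requested context level and
#' records the pre-threshold (sub-threshold) membrane potentials of the
#' penultimate activation layer — the last LIF layer before the
#' leaky-integrator readout — at every timestep. Each trial (sample) gets its
#' own frozen perturbation realization, derived deterministically from
#' `draw_seed` and logged, so perturbed records reflect across-trial draw
#' variability exactly as batched evaluation reflects across-batch draws.
#'
#' @param model an `snn_fit` or `snn_network`.
#' @param dataset an `snn_data`; for classification tasks, trial class
#'   labels are carried into the records.
#' @param contexts context levels to probe (the train-to-max models are
#'   typically probed at 0, 0.2 and 1).
#' @param spec perturbation model.
#' @param draw_seed seed of the per-context perturbation draws.
#' @return list of `trajectory_record` objects, one per context: each holds
#'   `potentials` (trials x timesteps x units), `labels`, `context`,
#'   `variant` and `draw_seed`.
#' @export
record_trajectories <- function(model, dataset, contexts = c(0, 0.2, 1),
                                spec = gaussian_spec(), draw_seed = 1) {
  net <- if (inherits(model, "snn_fit")) model$network else model
  n <- n_samples(dataset)
  labels <- if (dataset$task == "toyclass") dataset$labels else rep(NA_integer_, n)
  lapply(seq_along(contexts), function(i) {
    cc <- contexts[i]
    draw <- if (cc > 0) perturbation_draw(draw_seed + 1000L * i,
                                          per_sample = TRUE) else NULL
    ft <- forward_trial(net, dataset$frames, c = cc, spec = spec,
                        draw = draw, record = TRUE)
    pot <- ft$potentials
    if (all(pot == 0))
      warning(sprintf("degenerate record at context %g: all potentials zero", cc))
    structure(list(potentials = pot, labels = labels, context = cc,
                   variant = net$variant, mod_mode = net$mod_mode,
                   draw_seed = if (is.null(draw)) NA_integer_ else draw$seed),
              class = "trajectory_record")
  })
}

#' @export
print.trajectory_record <- function(x, ...) {
  d <- dim(x$potentials)
  cat(sprintf("trajectory_record: %d trials x %d timesteps x %d units (%s, context %g)\n",
              d[1], d[2], d[3], x$variant, x$context))
  invisible(x)
}

#' PCA embedding of latent trajectories
#'
#' Fits one PCA per condition on the pooled (trial x timestep) matrix of
#' membrane potentials, then projects each trial's timecourse into component
#' space, so trajectories of different trials share one coordinate system
#' and their locations are comparable across trials. Component signs follow
#' a fixed convention (the largest-magnitude loading of each component is
#' positive), making the embedding deterministic for a fixed record.
#'
#' @param record a `trajectory_record`.
#' @param n_components number of components (default 2).
#' @return object of class `snn_embedding`: `trajectories`
#'   (trials x timesteps x components), `loadings`, `explained` (variance
#'   ratios, non-increasing), `center`, plus the record's labels/context.
#' @export
pca_trajectories <- function(record, n_components = 2) {
  d <- dim(record$potentials)
  check_that(d[1] >= 2, "need at least 2 trials")
  X <- matrix(record$potentials, d[1] * d[2], d[3])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("rank-deficient input: returning %d of %d components",
                    k, n_components))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each loading is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  proj <- sweep(X, 2, pc$center) %*% load
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(trajectories = array(proj, c(d[1], d[2], k)),
                 loadings = load, explained = expl[seq_len(k)],
                 explained_all = expl, center = pc$center,
                 labels = record$labels, context = record$context,
                 variant = record$variant),
            class = "snn_embedding")
}

#' @export
print.snn_embedding <- function(x, ...) {
  d <- dim(x$trajectories)
  cat(sprintf("snn_embedding: %d trials x %d timesteps, %d components (%.1f%% / %.1f%% variance)\n",
              d[1], d[2], d[3], 100 * x$explained[1],
              if (d[3] > 1) 100 * x$explained[2] else NA))
  invisible(x)
}

#' Trajectory plot of a 2-D embedding, colored by timestep
#' @param x an `snn_embedding`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.snn_embedding <- function(x, ...) {
  tr <- x$trajectories
  d <- dim(tr)
  check_that(d[3] >= 2, "need a 2-D embedding to plot")
  graphics::plot(range(tr[, , 1]), range(tr[, , 2]), type = "n",
                 xlab = "PC1", ylab = "PC2",
                 main = sprintf("%s, context %g", x$variant, x$context), ...)
  cols <- grDevices::hcl.colors(d[2], "viridis")
  for (i in seq_len(d[1])) {
    graphics::lines(tr[i, , 1], tr[i, , 2], col = "grey70")
    graphics::points(tr[i, , 1], tr[i, , 2], col = cols, pch = 16, cex = 0.5)
  }
  invisible(x)
}

#' Class separation of final-timestep embedding positions
#'
#' Silhouette-style score over the final-timestep positions of each trial,
#' grouped by class: for each trial, `a` is its mean distance to same-class
#' trials and `b` the smallest mean distance to another class, scored as
#' `(b - a) / max(a, b)` and averaged. 1 means tight, well-separated class
#' clusters; 0 or below means classes are not separated. Distances are
#' Euclidean, so the score is invariant to rigid rotations of the embedding.
#'
#' @param embedding an `snn_embedding` (or a trials x components matrix of
#'   final positions).
#' @param labels class label per trial; defaults to the embedding's labels.
#' @return mean silhouette score in `[-1, 1]`.
#' @export
class_separation <- function(embedding, labels = NULL) {
  if (inherits(embedding, "snn_embedding")) {
    tr <- embedding$trajectories
    pos <- matrix(tr[, dim(tr)[2], ], dim(tr)[1], dim(tr)[3])
    if (is.null(labels)) labels <- embedding$labels
  } else pos <- as.matrix(embedding)
  check_that(!is.null(labels) && length(unique(labels)) >= 2,
             "need at least 2 classes")
  n <- nrow(pos)
  D <- as.matrix(stats::dist(pos))
  s <- vapply(seq_len(n), function(i) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    if (length(same) == 0) return(0)
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    m <- max(a, b)
    if (m == 0) 0 else (b - a) / m
  }, numeric(1))
  mean(s)
}

#' Summary statistics of learned adaptive projections
#'
#' Groups learned `p` vectors by the maximum perturbation level the network
#' was trained to, and reports per-group means with a one-sample location
#' test against zero plus pairwise two-sample distribution tests between
#' groups, all Bonferroni-corrected across the full set of comparisons.
#'
#' @param p_groups named list of numeric vectors; names are the training
#'   `c_max` values (or any group label).
#' @param alpha nominal significance level before correction.
#' @return object of class `p_stats`: list with `groups` (per-group n, mean,
#'   sd, t-test p raw and Bonferroni-corrected), `pairwise`
#'   (Kolmogorov-Smirnov p raw/corrected per pair), `alpha_nominal`,
#'   `alpha_corrected`, `n_comparisons`.
#' @export
p_distribution_stats <- function(p_groups, alpha = 0.05) {
  check_that(is.list(p_groups) && length(p_groups) >= 1,
             "p_groups must be a non-empty list")
  if (is.null(names(p_groups)))
    names(p_groups) <- seq_along(p_groups)
  gs <- data.frame(group = names(p_groups),
                   n = vapply(p_groups, length, integer(1)),
                   mean = vapply(p_groups, mean, numeric(1)),
                   sd = vapply(p_groups, stats::sd, numeric(1)),
                   row.names = NULL)
  gs$t_p <- vapply(p_groups, function(p) {
    if (length(p) < 2 || stats::sd(p) == 0) {
      if (all(p == 0)) 1 else NA_real_
    } else stats::t.test(p, mu = 0)$p.value
  }, numeric(1))
  pairs <- if (length(p_groups) >= 2) utils::combn(names(p_groups), 2) else NULL
  pw <- NULL
  if (!is.null(pairs)) {
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
    pw$ks_p <- vapply(seq_len(ncol(pairs)), function(j)
      suppressWarnings(stats::ks.test(p_groups[[pairs[1, j]]],
                                      p_groups[[pairs[2, j]]])$p.value),
      numeric(1))
  }
  n_comp <- nrow(gs) + if (is.null(pw)) 0 else nrow(pw)
  gs$t_p_bonf <- pmin(gs$t_p * n_comp, 1)
  if (!is.null(pw)) pw$ks_p_bonf <- pmin(pw$ks_p * n_comp, 1)
  structure(list(groups = gs, pairwise = pw, alpha_nominal = alpha,
                 alpha_corrected = alpha / n_comp, n_comparisons = n_comp),
            class = "p_stats")
}

#' @export
print.p_stats <- function(x, ...) {
  cat(sprintf("Adaptive-projection statistics (%d comparisons, corrected alpha %.4g)\n",
              x$n_comparisons, x$alpha_corrected))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise distribution tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Persist / restore trajectory records
#' @param records list of `trajectory_record` (or a single one).
#' @param path file path (`.rds`).
#' @return `save_trajectories` returns `path` invisibly.
#' @export
save_trajectories <- function(records, path) {
  saveRDS(records, path)
  invisible(path)
}

#' @rdname save_trajectories
#' @export
load_trajectories <- function(path) readRDS(path)
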