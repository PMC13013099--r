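#' Evaluate a trained model at one test perturbation level
#'
#' Runs the hold-out set through the network with `n_draws` independent
#' trial-frozen perturbation draws at the requested level and averages the
#' metric over draws (one batch = one trial; a fresh frozen draw per batch).
#' The context input to modulated (sham/context) variants equals the test
#' level. The metric is top-1 accuracy for classification heads and
#' mean squared error in squared pixels for tracking heads.
#'
#' @param model an `snn_fit` or `snn_network`.
#' @param dataset hold-out `snn_data`.
#' @param test_level test perturbation level; must lie on the level grid of
#'   `spec`.
#' @param spec perturbation model ([gaussian_spec()] or [dose_spec()]).
#' @param n_draws number of independent perturbation draws averaged.
#' @param seed seed of the evaluation draw stream.
#' @param batch_size evaluation batch (trial) size.
#' @return mean metric over draws, with per-draw values in attribute
#'   `"draws"`.
#' @export
evaluate_model <- function(model, dataset, test_level, spec = gaussian_spec(),
                           n_draws = 5, seed = 1, batch_size = 16) {
  net <- if (inherits(model, "snn_fit")) model$network else model
  lv <- context_levels(spec)
  check_that(any(abs(lv - test_level) < 1e-9),
             "test_level must lie on the perturbation level grid")
  n <- n_samples(dataset)
  nb <- ceiling(n / batch_size)
  dseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_draws))
  per_draw <- vapply(seq_len(n_draws), function(d) {
    vals <- numeric(nb); wts <- numeric(nb)
    for (ib in seq_len(nb)) {
      idx <- ((ib - 1) * batch_size + 1):min(ib * batch_size, n)
      batch <- get_batch(dataset, idx)
      draw <- if (test_level > 0)
        perturbation_draw(dseeds[d] %% (.Machine$integer.max - nb) + ib)
      else NULL
      out <- forward_trial(net, batch$frames, c = test_level, spec = spec,
                           draw = draw)
      vals[ib] <- metric_value(net, out, batch, dataset)
      wts[ib] <- length(idx)
    }
    sum(vals * wts) / sum(wts)
  }, numeric(1))
  structure(mean(per_draw), draws = per_draw)
}

metric_value <- function(net, out, batch, dataset) {
  if (net$config$head == "classification") {
    mean(max.col(out, ties.method = "first") == batch$target)
  } else {
    # squared pixel units: undo the [0, 1] coordinate normalization
    H <- dataset$config$height; W <- dataset$config$width
    err <- out - batch$target
    err[, , 1] <- err[, , 1] * (W - 1)
    err[, , 2] <- err[, , 2] * (H - 1)
    mean(err^2)
  }
}

#' Run the train-by-test perturbation sweep grid
#'
#' Evaluates every supplied trained model at every test level, producing the
#' full rectangular (variant, training c_max, test level, seed, draw) grid
#' of metrics. Cells are cached on disk (keyed by their coordinates) so an
#' interrupted sweep resumes without recomputation; a model missing from
#' `models` leaves its cells absent (with a warning) and the run continues.
#'
#' @param models named list of `snn_fit` objects. Names follow
#'   `"<variant>|<mod_mode>|<c_max>|<seed>"` (see [grid_key()]).
#' @param dataset hold-out dataset (disjoint, by generation seed, from the
#'   training data).
#' @param test_levels test perturbation levels.
#' @param spec perturbation model.
#' @param n_draws perturbation draws per cell.
#' @param cache_dir optional directory for per-cell caching.
#' @param batch_size evaluation batch size.
#' @return object of class `sweep_grid`: a long-format data.frame with
#'   columns `variant, mod, cmax, test_level, seed, draw, metric` and the
#'   sweep metadata as attributes.
#' @export
run_grid <- function(models, dataset, test_levels, spec = gaussian_spec(),
                     n_draws = 5, cache_dir = NULL, batch_size = 16) {
  check_that(length(models) >= 1 && !is.null(names(models)),
             "models must be a named list (see grid_key)")
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (key in names(models)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    check_that(length(parts) == 4, sprintf("malformed model key '%s'", key))
    if (is.null(models[[key]])) {
      warning(sprintf("missing checkpoint for %s; cells left absent", key))
      next
    }
    for (tl in test_levels) {
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", key),
                                    "_t", tl, ".rds"))
      if (!is.null(cache_file) && file.exists(cache_file)) {
        cell <- readRDS(cache_file)
      } else {
        eseed <- cell_seed(key, tl)
        m <- evaluate_model(models[[key]], dataset, tl, spec = spec,
                            n_draws = n_draws, seed = eseed,
                            batch_size = batch_size)
        cell <- data.frame(variant = parts[1], mod = parts[2],
                           cmax = as.numeric(parts[3]),
                           test_level = tl,
                           seed = as.integer(parts[4]),
                           draw = seq_len(n_draws),
                           metric = attr(m, "draws"),
                           draw_seed = eseed)
        if (!is.null(cache_file)) saveRDS(cell, cache_file)
      }
      rows[[length(rows) + 1]] <- cell
    }
  }
  g <- do.call(rbind, rows)
  rownames(g) <- NULL
  structure(g, class = c("sweep_grid", "data.frame"),
            metric_name = if (models[[1]]$network$config$head == "classification")
              "top1_accuracy" else "mse_pixels2",
            n_draws = n_draws, test_levels = test_levels,
            spec_model = spec$model)
}

#' Key of one trained checkpoint in a sweep
#' @param variant,mod_mode,c_max,seed cell coordinates.
#' @return character key `"variant|mod|cmax|seed"`.
#' @export
grid_key <- function(variant, mod_mode, c_max, seed)
  paste(variant, mod_mode, c_max, seed, sep = "|")

# deterministic per-cell evaluation seed derived from the cell coordinates
cell_seed <- function(key, test_level) {
  s <- utf8ToInt(paste0(key, "@", format(test_level)))
  as.integer((sum(as.double(s) * seq_along(s)) * 2654435) %%
               (.Machine$integer.max - 2) + 1)
}

#' Aggregate a sweep grid over draws (and optionally seeds)
#'
#' @param grid a `sweep_grid`.
#' @param over `"draws"` keeps per-seed cell means; `"seeds"` also averages
#'   the seed replicates, giving the headline grid.
#' @return data.frame of cell means.
#' @export
grid_cells <- function(grid, over = c("draws", "seeds")) {
  over <- match.arg(over)
  by <- list(variant = grid$variant, mod = grid$mod, cmax = grid$cmax,
             test_level = grid$test_level)
  if (over == "draws") by$seed <- grid$seed
  agg <- stats::aggregate(list(metric = grid$metric), by = by, FUN = mean)
  agg[do.call(order, agg[setdiff(names(agg), "metric")]), , drop = FALSE]
}

#' Write / read a sweep grid (long-format CSV + JSON manifest)
#'
#' Metrics are serialized with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param grid a `sweep_grid`.
#' @param path CSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return `write_grid` returns `path` invisibly; `read_grid` the restored
#'   `sweep_grid`.
#' @export
write_grid <- function(grid, path) {
  df <- as.data.frame(grid)
  df$metric <- sprintf("%.17g", df$metric)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(metric_name = attr(grid, "metric_name"),
                   n_draws = attr(grid, "n_draws"),
                   test_levels = attr(grid, "test_levels"),
                   spec_model = attr(grid, "spec_model"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$metric <- as.numeric(df$metric)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  structure(df, class = c("sweep_grid", "data.frame"),
            metric_name = man$metric_name, n_draws = man$n_draws,
            test_levels = man$test_levels, spec_model = man$spec_model)
}

#' @export
print.sweep_grid <- function(x, ...) {
  cells <- grid_cells(x, over = "seeds")
  cat(sprintf("sweep_grid: %d cells (%s), %d draws/cell, levels [%s]\n",
              nrow(grid_cells(x)), attr(x, "metric_name"),
              attr(x, "n_draws"),
              paste(attr(x, "test_levels"), collapse = ", ")))
  print(cells, row.names = FALSE)
  invisible(x)
}

#' Heatmap of a sweep grid (training c_max by test level)
#'
#' One panel per (variant, mod) combination, seed-averaged.
#'
#' @param x a `sweep_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_grid <- function(x, ...) {
  cells <- grid_cells(x, over = "seeds")
  combos <- unique(cells[c("variant", "mod")])
  op <- graphics::par(mfrow = c(1, nrow(combos)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(combos))) {
    sub <- cells[cells$variant == combos$variant[i] & cells$mod == combos$mod[i], ]
    cm <- sort(unique(sub$cmax)); tl <- sort(unique(sub$test_level))
    m <- matrix(NA_real_, length(cm), length(tl))
    m[cbind(match(sub$cmax, cm), match(sub$test_level, tl))] <- sub$metric
    graphics::image(seq_along(tl), seq_along(cm), t(m), axes = FALSE,
                    xlab = "test level", ylab = "training c_max",
                    main = paste(combos$variant[i], combos$mod[i]), ...)
    graphics::axis(1, seq_along(tl), tl)
    graphics::axis(2, seq_along(cm), cm)
  }
  invisible(x)
}
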