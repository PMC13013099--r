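#' Gaussian weight-perturbation model
#'
#' Multiplicative-magnitude Gaussian perturbation of synaptic weights:
#' \deqn{w' = w + c\,|w|\,\varphi, \qquad \varphi \sim N(0,1)}
#' drawn i.i.d. once per trial and held constant over all timesteps within
#' the trial (slow drift, not fast stochasticity). The level `c` doubles as
#' the global context scalar. Ten evenly spaced levels on [0, 1] form the
#' default evaluation grid.
#'
#' @param level_grid ordered vector of perturbation levels in [0, 1].
#' @return object of class `gaussian_spec`.
#' @export
gaussian_spec <- function(level_grid = seq(0, 1, length.out = 10)) {
  check_that(!is.unsorted(level_grid), "level_grid must be sorted")
  check_that(all(level_grid >= 0 & level_grid <= 1), "levels must lie in [0, 1]")
  structure(list(model = "gaussian", level_grid = level_grid),
            class = c("gaussian_spec", "perturb_spec"))
}

#' Dose-dependent (total-ionizing-dose) weight-perturbation model
#'
#' Device-style perturbation of weights stored in analog charge-trap memory
#' exposed to ionizing radiation: for a stored weight `w` at cumulative dose
#' `d` (krad), the perturbation is \eqn{N(\mu(w,d), \sigma(w,d))} with the
#' mean and spread surfaces read from a rectangular lookup table and
#' bilinearly interpolated. At dose 0 only the intrinsic write-error spread
#' applies. The context scalar fed to the network is `dose / max(dose_grid)`.
#'
#' @param table a `dose_table` from [dose_table_load()] or
#'   [synthetic_dose_table()]. Defaults to the synthetic table shipped with
#'   the package.
#' @param dose_grid evaluation doses in krad; default 0 to 1,000 krad in
#'   100 krad steps.
#' @return object of class `dose_spec`.
#' @export
dose_spec <- function(table = NULL, dose_grid = seq(0, 1000, by = 100)) {
  if (is.null(table))
    table <- dose_table_load(system.file("extdata", "sonos_tid_synthetic.csv",
                                         package = "contextsnn"))
  check_that(inherits(table, "dose_table"), "table must be a dose_table")
  check_that(!is.unsorted(dose_grid) && all(dose_grid >= 0),
             "dose_grid must be sorted and non-negative")
  check_that(min(dose_grid) >= min(table$dose) && max(dose_grid) <= max(table$dose),
             "dose_grid must be covered by the lookup table")
  structure(list(model = "dose", table = table, dose_grid = dose_grid),
            class = c("dose_spec", "perturb_spec"))
}

#' Load a dose-dependent perturbation lookup table
#'
#' The file is a CSV with header `weight,dose_krad,mu,sigma` forming a
#' rectangular (weight x dose) grid; `mu` is the deterministic (mean)
#' component of the perturbation at that point and `sigma` the random
#' component's standard deviation. Validated on load.
#'
#' @param path CSV path.
#' @return object of class `dose_table` with sorted `weight` and `dose`
#'   grids and `mu`, `sigma` matrices (weights x doses).
#' @export
dose_table_load <- function(path) {
  check_that(file.exists(path), paste("no such table file:", path))
  df <- utils::read.csv(path)
  check_that(identical(sort(names(df)), sort(c("weight", "dose_krad", "mu", "sigma"))),
             "table must have columns weight,dose_krad,mu,sigma")
  dose_table(df$weight, df$dose_krad, df$mu, df$sigma)
}

# Build and validate a dose_table from long-format vectors.
dose_table <- function(weight, dose_krad, mu, sigma) {
  w <- sort(unique(weight)); d <- sort(unique(dose_krad))
  check_that(length(weight) == length(w) * length(d),
             "table grid is not rectangular (weight x dose)")
  check_that(all(is.finite(mu)) && all(is.finite(sigma)), "mu/sigma must be finite")
  check_that(all(sigma >= 0), "sigma must be non-negative everywhere")
  check_that(length(w) >= 2 && length(d) >= 2, "grid needs at least 2 x 2 points")
  key <- paste(match(weight, w), match(dose_krad, d))
  check_that(!anyDuplicated(key), "duplicate (weight, dose) entries in table")
  mu_m <- matrix(NA_real_, length(w), length(d))
  sg_m <- matrix(NA_real_, length(w), length(d))
  mu_m[cbind(match(weight, w), match(dose_krad, d))] <- mu
  sg_m[cbind(match(weight, w), match(dose_krad, d))] <- sigma
  check_that(!anyNA(mu_m), "table grid is not rectangular (missing cells)")
  structure(list(weight = w, dose = d, mu = mu_m, sigma = sg_m),
            class = "dose_table")
}

#' Synthetic dose-dependent perturbation table
#'
#' A configurable stand-in for empirical device characterization: the mean
#' perturbation drifts each weight toward a saturation value with
#' exponentially saturating dose dependence, and the spread grows modestly
#' with dose on top of an intrinsic write-error floor. Qualitative behavior:
#' dose-increasing mean shift toward saturation, modest spread growth, and
#' at dose 0 only write error. The table is synthetic; it is not fit to any
#' measured device data.
#'
#' @param weight_grid stored-weight grid the table covers.
#' @param dose_grid dose grid in krad.
#' @param w_sat saturation weight the mean drifts toward.
#' @param dose_scale dose constant (krad) of the exponential saturation.
#' @param write_error_sigma spread at dose 0 (intrinsic write error).
#' @param sigma_rad additional spread at full saturation.
#' @return a `dose_table`.
#' @export
synthetic_dose_table <- function(weight_grid = seq(-1, 1, by = 0.25),
                                 dose_grid = seq(0, 1000, by = 100),
                                 w_sat = 0, dose_scale = 400,
                                 write_error_sigma = 0.02, sigma_rad = 0.05) {
  g <- expand.grid(weight = weight_grid, dose_krad = dose_grid)
  sat <- 1 - exp(-g$dose_krad / dose_scale)
  mu <- (w_sat - g$weight) * sat
  sigma <- write_error_sigma + sigma_rad * sat * (0.5 + 0.5 * abs(g$weight))
  dose_table(g$weight, g$dose_krad, mu, sigma)
}

# Bilinear interpolation on a dose_table. Returns mu, sigma and their
# partial derivatives in w (needed for gradient flow through perturbed
# weights during training).
dose_interp <- function(table, w, dose) {
  check_that(dose >= min(table$dose) && dose <= max(table$dose),
             "dose outside the lookup-table range")
  wr <- range(table$weight)
  wc <- pmin(pmax(w, wr[1]), wr[2])  # weights beyond the table edge use edge values
  iw <- findInterval(wc, table$weight, rightmost.closed = TRUE)
  iw <- pmin(pmax(iw, 1L), length(table$weight) - 1L)
  id <- findInterval(dose, table$dose, rightmost.closed = TRUE)
  id <- min(max(id, 1L), length(table$dose) - 1L)
  w0 <- table$weight[iw]; w1 <- table$weight[iw + 1L]
  d0 <- table$dose[id]; d1 <- table$dose[id + 1L]
  tw <- (wc - w0) / (w1 - w0)
  td <- (dose - d0) / (d1 - d0)
  bil <- function(m) {
    a <- m[cbind(iw, id)] * (1 - tw) + m[cbind(iw + 1L, id)] * tw
    b <- m[cbind(iw, id + 1L)] * (1 - tw) + m[cbind(iw + 1L, id + 1L)] * tw
    a * (1 - td) + b * td
  }
  dbil <- function(m) {
    a <- (m[cbind(iw + 1L, id)] - m[cbind(iw, id)]) / (w1 - w0)
    b <- (m[cbind(iw + 1L, id + 1L)] - m[cbind(iw, id + 1L)]) / (w1 - w0)
    d <- a * (1 - td) + b * td
    d[w < wr[1] | w > wr[2]] <- 0  # flat extension outside the grid
    d
  }
  list(mu = bil(table$mu), sigma = bil(table$sigma),
       dmu_dw = dbil(table$mu), dsigma_dw = dbil(table$sigma))
}

#' Create a trial-frozen perturbation draw
#'
#' A draw identifies one noise realization: realized tensors are a pure
#' function of `(seed, tensor name, tensor shape)`, so applying the same
#' draw twice yields identical perturbed weights, and the realization is
#' constant across all timesteps within a trial by construction.
#'
#' @param seed integer seed of the draw.
#' @param per_sample logical; if `TRUE`, downstream forward passes realize
#'   an independent perturbation per sample within the batch instead of one
#'   shared realization per trial/batch.
#' @return object of class `perturbation_draw`.
#' @export
perturbation_draw <- function(seed, per_sample = FALSE) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed must be a single finite number")
  structure(list(seed = as.integer(seed), per_sample = isTRUE(per_sample)),
            class = "perturbation_draw")
}

#' Realize standard-normal noise tensors for a draw
#'
#' @param draw a [perturbation_draw()].
#' @param shapes named list of dimension vectors (one per weight tensor).
#' @return named list of arrays of i.i.d. standard normals.
#' @export
draw_phi <- function(draw, shapes) {
  check_that(inherits(draw, "perturbation_draw"), "draw must be a perturbation_draw")
  with_seed(draw$seed, {
    out <- vector("list", length(shapes))
    names(out) <- names(shapes)
    for (i in seq_along(shapes)) {
      d <- shapes[[i]]
      out[[i]] <- array(stats::rnorm(prod(d)), dim = d)
    }
    out
  })
}

#' Apply the Gaussian perturbation model to a weight tensor
#'
#' Non-destructive: returns a perturbed copy, leaving the ideal weights
#' untouched and recoverable.
#'
#' @param weights numeric array/matrix/vector of ideal weights.
#' @param c perturbation level (>= 0).
#' @param phi standard-normal array of the same shape (the frozen trial
#'   realization), e.g. one element of [draw_phi()].
#' @return perturbed weights, same shape.
#' @export
perturb_gaussian <- function(weights, c, phi) {
  check_that(is.numeric(c) && length(c) == 1 && c >= 0,
             "perturbation level c must be a single value >= 0")
  check_that(length(phi) == length(weights), "phi must match the weight shape")
  weights + c * abs(weights) * phi
}

#' Apply the dose-dependent perturbation model to a weight tensor
#'
#' @param weights numeric array of ideal weights.
#' @param spec a [dose_spec()].
#' @param dose dose in krad, within the table range.
#' @param phi standard-normal array of the same shape.
#' @return perturbed weights `w + mu(w, dose) + sigma(w, dose) * phi`.
#' @export
perturb_dose <- function(weights, spec, dose, phi) {
  check_that(inherits(spec, "dose_spec"), "spec must be a dose_spec")
  check_that(length(phi) == length(weights), "phi must match the weight shape")
  ip <- dose_interp(spec$table, as.numeric(weights), dose)
  out <- weights + ip$mu + ip$sigma * as.numeric(phi)
  if (is.array(weights)) dim(out) <- dim(weights)
  out
}

#' Context-level grid of a perturbation model
#'
#' The discrete levels at which models are trained and evaluated, expressed
#' as context scalars in `[0, 1]` (for the dose model, dose divided by the
#' maximum dose of the grid).
#'
#' @param spec a perturbation spec, or `NULL` (returns 0).
#' @return numeric vector of levels.
#' @export
context_levels <- function(spec) {
  if (is.null(spec)) return(0)
  if (inherits(spec, "gaussian_spec")) spec$level_grid
  else spec$dose_grid / max(spec$dose_grid)
}

# Unified perturbation application used by network forward/backward passes.
# `level` is the context scalar in [0, 1]; for the dose model it maps to
# dose = level * max(dose_grid). Returns the perturbed tensor and the
# derivative d w'/d w needed to route gradients to the ideal weights.
apply_perturbation <- function(spec, level, weights, phi) {
  if (inherits(spec, "gaussian_spec")) {
    list(w = weights + level * abs(weights) * phi,
         dw = 1 + level * sign(weights) * phi)
  } else if (inherits(spec, "dose_spec")) {
    dose <- level * max(spec$dose_grid)
    ip <- dose_interp(spec$table, as.numeric(weights), dose)
    w <- weights + ip$mu + ip$sigma * as.numeric(phi)
    dw <- 1 + ip$dmu_dw + ip$dsigma_dw * as.numeric(phi)
    if (is.array(weights)) { dim(w) <- dim(weights); dim(dw) <- dim(weights) }
    list(w = w, dw = dw)
  } else stop("unknown perturbation spec", call. = FALSE)
}

#' Grouped shift/spread summary of a perturbed weight tensor
#'
#' Groups weights by their distinct target (pre-perturbation) value and
#' reports the empirical mean shift and spread around each target —
#' the numerical counterpart of per-target weight histograms. Intended for
#' probe tensors with a small set of repeated target values; continuous
#' weights can be grouped after rounding via `digits`.
#'
#' @param weights_before ideal weights.
#' @param weights_after perturbed weights (same shape).
#' @param digits optional rounding applied to targets before grouping.
#' @return data.frame with columns `target`, `n`, `mean_shift`, `spread`.
#' @export
weight_distribution_stats <- function(weights_before, weights_after,
                                      digits = NULL) {
  check_that(length(weights_before) == length(weights_after),
             "weight tensors must have matching shapes")
  tgt <- as.numeric(weights_before)
  if (!is.null(digits)) tgt <- round(tgt, digits)
  shift <- as.numeric(weights_after) - as.numeric(weights_before)
  groups <- split(shift, tgt)
  targets <- as.numeric(names(groups))
  data.frame(
    target = targets,
    n = vapply(groups, length, integer(1)),
    mean_shift = vapply(groups, mean, numeric(1)),
    spread = vapply(groups, function(g) if (length(g) > 1) stats::sd(g) else 0,
                    numeric(1)),
    row.names = NULL
  )[order(targets), , drop = FALSE]
}
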