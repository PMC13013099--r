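#' Derive independent seed streams from a master seed
#'
#' Experiments use three independent sources of randomness: dataset
#' generation, parameter initialization, and perturbation draws. Deriving
#' them from one master seed keeps a whole experiment reproducible from a
#' single integer while allowing any one stream (e.g. the perturbation
#' draws) to be varied with the others held fixed.
#'
#' @param seed single integer master seed.
#' @return named list with integer elements `data`, `init`, `perturb`.
#' @export
seed_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, 3L))
  list(data = s[1], init = s[2], perturb = s[3])
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws (perturbations,
#' dataset generation) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# stopifnot() with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
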