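#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package operations do
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive per-stage seeds from one root seed
#'
#' One root seed deterministically spawns named sub-seeds so pipeline stages
#' can be re-run in isolation. All spawned seeds stay below 2^31.
#'
#' @param seed integer root seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds.
#' @export
spawn_seeds <- function(seed, stages) {
  stopifnot(is.character(stages), length(stages) >= 1L)
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(stages)))
  names(s) <- stages
  s
}

# Internal: stop() with a consistent prefix for user-facing validation errors.
fail <- function(...) stop(sprintf(...), call. = FALSE)
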