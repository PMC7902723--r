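#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls never perturb a user's random
#' stream.  A `NULL` seed evaluates the code against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Splittable counter scheme: one global seed fans out to per-stage child
#' seeds, so adding a stage never perturbs the draws of earlier stages.
#' Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed parent integer seed.
#' @param stage integer stage tag.
#' @param index integer counter within the stage.
#' @return integer seed.
#' @export
child_seed <- function(seed, stage = 0L, index = 0L) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + as.numeric(stage) * 16807 + as.numeric(index)) %% m
  x <- (x * 69621 + 1) %% m
  as.integer(x %% (m - 1) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 0

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
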