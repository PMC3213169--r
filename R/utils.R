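# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' session's random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# stop() with call. = FALSE and sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# linear interpolation of a trajectory defined on a knot grid; constant
# extrapolation is deliberately NOT allowed -- callers must stay in range
traj_at <- function(times, values, t) {
  if (t < min(times) || t > max(times))
    abort("time %g min is outside the modeled window [%g, %g]",
          t, min(times), max(times))
  stats::approx(times, values, xout = t)$y
}
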