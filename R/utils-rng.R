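#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the global random number generator seeded at
#' \code{seed}, then restores the caller's RNG state, so that simulation
#' functions are reproducible without clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' All randomness in the simulators flows from one integer seed; substreams
#' (per field, per gene, per replicate) use deterministic children computed as
#' \code{(seed * 48271 + k) mod (2^31 - 1)}, a multiplicative congruential
#' step that keeps every derived seed a valid 32-bit integer.
#'
#' @param seed master integer seed.
#' @param k nonnegative integer substream index.
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271 + as.numeric(k)) %% (m - 1)) + 1)
}
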