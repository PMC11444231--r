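# Seed plumbing: every stochastic entry point runs under a locally-set seed
# and restores the caller's RNG state, so library code never perturbs the
# global stream.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the RNG, evaluates `code`, and
#' restores the previous state on exit. Used internally by every function
#' that accepts a `seed` argument.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a per-participant substream seed from a master seed
#'
#' Counter-based split: participant `counter` under `master_seed` always gets
#' the same seed, so changing one arm's sample size never reshuffles the
#' draws of any other participant. Two rounds of a multiplicative-congruential
#' mix modulo the prime 2^31 - 1; all intermediates stay below 2^53 so the
#' arithmetic is exact in doubles.
#'
#' @param master_seed Non-negative integer master seed (< 2^31).
#' @param counter Non-negative integer stream counter.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
#' @export
derive_seed <- function(master_seed, counter) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, master_seed >= 0,
            is.numeric(counter), length(counter) == 1, counter >= 0)
  p <- 2147483647  # 2^31 - 1, prime
  h <- (master_seed %% p) * 69069 + counter + 1
  h <- h %% p
  h <- (h * 69069 + 12345) %% p
  h <- (h * 40503 + 1) %% p
  as.integer(if (h == 0) 1 else h)
}
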