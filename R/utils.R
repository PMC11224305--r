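# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates in the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}

#' Derive a stage seed from a global seed
#'
#' Deterministic counter scheme used throughout the package: each named stage
#' of a run draws its own seed from the single global seed, so stages can be
#' re-run independently while the whole run stays reproducible. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param salt Stage name (string) or integer counter.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  h <- if (is.character(salt)) sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt))) else as.numeric(salt)
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((x + h * 69621) %% (m - 1) + 1)
}
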