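#' @include AllClasses.R
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible stream of sub-seeds (< 2^31) from a base seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# assert helper producing uniform error messages
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
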