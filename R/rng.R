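# Deterministic per-module random streams derived from one master seed.
#
# Stochastic pieces of an experiment (cell initialisation, expression noise,
# camera noise, recombination draws, ...) each draw from their own stream so
# that changing one module's consumption pattern does not perturb the others
# and identical configs replay identically.

#' Derive a labelled stream seed from a master seed
#'
#' Uses a small multiplicative string hash folded into the master seed,
#' reduced modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param label character stream label (e.g. `"camera"`, `"ssa"`).
#' @return integer seed, deterministic in `(master, label)`.
#' @export
deriveSeed <- function(master, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(as.numeric(master)) * 2654435 + h) %% 2147483647)
}

#' Create a set of named RNG streams
#'
#' Each stream is an independent Mersenne-Twister state seeded via
#' [deriveSeed()]. `withStream()` evaluates an expression while the global
#' RNG is swapped to the stream, then saves the advanced state back, so
#' modules cannot perturb each other's randomness.
#'
#' @param master integer master seed.
#' @return an environment holding stream states.
#' @export
rngStreams <- function(master) {
  env <- new.env(parent = emptyenv())
  env$master <- as.integer(master)
  env$states <- list()
  env
}

#' @param streams environment from [rngStreams()].
#' @param label stream label.
#' @param expr expression to evaluate under the stream's RNG state.
#' @rdname rngStreams
#' @export
withStream <- function(streams, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (is.null(streams$states[[label]])) {
    set.seed(deriveSeed(streams$master, label))
  } else {
    assign(".Random.seed", streams$states[[label]], envir = globalenv())
  }
  on.exit({
    streams$states[[label]] <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
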