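#' Derive a named substream seed from a master seed
#'
#' All stochastic stages of the package draw their randomness from a single
#' master seed fanned out into named substreams, so that (a) a whole pipeline
#' run is reproducible from one integer and (b) any single stage can be
#' re-run in isolation with the same draws it saw inside the pipeline.
#'
#' The derivation is a small deterministic integer hash of the stream name
#' mixed with the master seed; it stays within the 32-bit signed range that
#' [set.seed()] accepts.
#'
#' @param master integer master seed.
#' @param name character scalar naming the substream (e.g. `"counts"`,
#'   `"hopkins"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "counts")
#' substream_seed(1, "hopkins")
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(name) == 1L, nzchar(name))
  h <- 0
  for (cc in utf8ToInt(name)) {
    h <- (h * 131 + cc) %% 2147483629
  }
  as.integer((abs(as.numeric(master)) %% 2147483629 * 31 + h) %% 2147483629)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state. Used internally so that seeded operations are pure functions of
# their arguments.
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}
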