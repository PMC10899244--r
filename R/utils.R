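# Seed handling: all stochastic entry points take an explicit seed and
# leave the caller's RNG state untouched.

withSeed <- function(seed, expr) {
  force(seed)   # evaluate any seed expression before the state snapshot
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed for a pipeline stage
#'
#' Deterministic fan-out of one master seed into per-stage seeds, so a
#' stage can be rerun in isolation with the seed the pipeline would have
#' used.  Always below 2^31.
#'
#' @param seed master seed (integer).
#' @param stage stage index (integer >= 0) or stage name.
#' @return integer child seed.
#' @export
childSeed <- function(seed, stage) {
  if (is.character(stage))
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %%
               2147483647)
}

rms <- function(x) sqrt(mean(x^2))
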