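# Reproducible, isolated RNG streams.
#
# A training run draws from two independent streams -- one for parameter
# initialization, one for per-epoch data shuffling and dropout masks -- so
# that e.g. changing the number of epochs never perturbs the initial
# weights. Each stream snapshots and restores .Random.seed around every
# draw, leaving the caller's global RNG untouched.

rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
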