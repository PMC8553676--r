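# internal helpers

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards.  seed = NULL runs in the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw k reproducible sub-seeds from the current RNG stream (kept < 2^31).
draw_seeds <- function(k) sample.int(.Machine$integer.max - 1L, k, replace = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
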