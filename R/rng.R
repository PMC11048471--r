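# Reproducible substreams via L'Ecuyer-CMRG.
#
# One master seed is expanded into one independent stream per patient and
# one substream per draw site (identity, reference, each probe
# condition).  Streams are advanced with parallel::nextRNGStream /
# nextRNGSubStream, which are pure functions of the seed vector, so
# patient i's draws never depend on the cohort size and adding patients
# never reshuffles existing ones.

# Convert an integer seed into an L'Ecuyer-CMRG .Random.seed vector
# without disturbing the caller's RNG state.
lecuyer_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  suppressWarnings(
    set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG",
             normal.kind = "Inversion")
  )
  get(".Random.seed", envir = globalenv())
}

# Evaluate fn() with the global RNG set to `stream`, restoring the
# caller's RNG state afterwards.  Returns fn()'s value.
with_stream <- function(stream, fn) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  fn()
}
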