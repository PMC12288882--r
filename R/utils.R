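# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fan a master seed out to per-stage seeds, keeping them in 32-bit range.
stage_seed <- function(rng_seed, stage) {
  offsets <- c(cluster = 11L, seeds = 23L, markers = 37L, simulate = 53L,
               folds = 71L, cv = 89L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(rng_seed) %% 1000000L) * 1000L + offsets[[stage]]
}
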