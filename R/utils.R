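## Run a seeded draw without disturbing the caller's RNG stream: the
## global .Random.seed is restored on exit, so Monte-Carlo loops that
## draw their own seeds between simulator calls see independent draws.
.snapshotRng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
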