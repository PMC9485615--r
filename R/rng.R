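# RNG plumbing: experiment drivers derive one seed per (trial, helmet, use)
# from the master seed, so that placed dipole sets are identical across
# compared helmets while noise realizations stay independent, and every run
# is reproducible end to end.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a child seed from a master seed and integer keys
#'
#' Deterministic mixing (multiplicative congruential steps modulo 2^31 - 1)
#' of a master seed with any number of integer keys, giving independent,
#' reproducible substreams for trials, helmets and noise draws.
#'
#' @param master Master seed (integer).
#' @param ... Integer keys (trial number, helmet serial, ...).
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m)
  for (key in c(...)) {
    x <- (x * 48271 + abs(as.numeric(key)) + 1) %% m
    x <- (x * 69621 + 12345) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}
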