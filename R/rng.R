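#' Per-iteration random-number substreams
#'
#' Reproducibility contract: a scenario owns one root seed, and iteration k
#' uses the k-th L'Ecuyer-CMRG substream derived from that seed. Each
#' iteration is therefore reproducible on its own and independent of how
#' many other iterations ran before it, which also makes the Monte Carlo
#' loop order-independent and safe to parallelise.
#'
#' `trial_stream(seed, k)` returns the RNG state for iteration k;
#' `trial_streams(seed, n)` returns states for iterations 1..n in one pass.
#'
#' @param seed Integer root seed.
#' @param k Iteration index (>= 1).
#' @param n Number of iterations.
#' @return A `.Random.seed`-style integer vector (or a list of them).
#' @export
trial_stream <- function(seed, k) {
  stopifnot(k >= 1)
  s <- root_stream(seed)
  for (i in seq_len(k)) s <- parallel::nextRNGStream(s)
  s
}

#' @rdname trial_stream
#' @export
trial_streams <- function(seed, n) {
  s <- root_stream(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

# RNG state obtained by seeding the CMRG generator with the root seed,
# without disturbing the caller's generator settings.
root_stream <- function(seed) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_kind <- RNGkind("L'Ecuyer-CMRG")
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    restore_rng_state(old_seed)
  })
  set.seed(as.integer(seed))
  get(".Random.seed", envir = globalenv())
}

# Evaluate `expr` with the RNG positioned at `state`, then restore the
# caller's RNG so library code does not perturb user-level randomness.
with_rng_state <- function(state, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", state, envir = globalenv())
  on.exit(restore_rng_state(old_seed))
  expr
}

restore_rng_state <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
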