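#' @keywords internal
"_PACKAGE"

# Seed/RNG plumbing. Model states own their RNG streams (a saved .Random.seed
# vector) so that training is resumable and federated clients draw independent
# randomness without touching the caller's RNG.

#' Evaluate an expression under a temporary seed
#'
#' Saves and restores the caller's RNG state, so seeded internals never
#' perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fresh RNG stream (a .Random.seed vector) initialised from `seed`.
rng_state_new <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  s
}

# Run `expr` with `state`'s RNG stream active; the advanced stream is written
# back into the state environment afterwards.
with_state_rng <- function(state, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", state$rng, envir = globalenv())
  on.exit({
    state$rng <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' A small multiplicative hash over the base seed and any number of extra
#' identifiers (numbers or strings). Used to give every experimental cell and
#' fold its own deterministic seed below 2^31.
#'
#' @param base integer base seed.
#' @param ... further numeric or character identifiers.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base, ...) {
  ids <- list(base, ...)
  h <- 0
  for (x in ids) {
    xs <- if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
    for (v in xs) h <- (h * 69069 + v + 1) %% 2147483629
  }
  as.integer(h %% 2147483628 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
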