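# Internal helpers: deterministic seed derivation and scoped RNG.

# Combine a user seed with index arguments into a reproducible 31-bit seed.
# Lehmer-style mixing keeps every derived seed in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 11) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# Collapse repeated whitespace left behind by string surgery.
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fail_with <- function(...) stop(sprintf(...), call. = FALSE)
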