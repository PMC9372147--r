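# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Small deterministic string hash onto [0, 2^31 - 2]; used to derive
# per-acquisition seeds from a base seed plus an identity string.
hash_seed <- function(base_seed, key) {
  h <- as.double(base_seed %% 2147483647)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Round half away from zero (the convention matching printed 3-dp tables,
# unlike base round()'s round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
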