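# Internal helpers: seed derivation, sigmoid, small validators.

# Deterministically derive a 31-bit seed from a master seed plus arbitrary
# tokens (integers or strings). Polynomial rolling hash mod a prime below
# 2^31; exact in double arithmetic since intermediates stay < 2^53.
derive_seed <- function(master, ...) {
  mod <- 2147483629
  h <- as.double(master) %% mod
  for (tok in list(...)) {
    units <- if (is.character(tok)) utf8ToInt(tok) else as.double(tok)
    for (u in units) h <- (h * 31 + (u %% mod) + 7) %% mod
  }
  as.integer(h) + 1L
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
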