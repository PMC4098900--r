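# Internal helpers: deterministic seed streams and RNG scoping.

# Derive a reproducible 31-bit sub-seed from a master seed and a path of
# integer indices (tumor, observer, run, ...). Linear-congruential mixing is
# enough here: we only need distinct, stable streams, not cryptography.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master %% 2147483647L)
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
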