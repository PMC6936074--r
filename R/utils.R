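`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic small-integer seed derivation (kept below 2^31).
derive_seed <- function(seed, a = 0, b = 0, c = 0) {
  v <- (as.double(seed) * 2654435761 + as.double(a) * 40503 +
        as.double(b) * 2971 + as.double(c) * 7) %% 2147483563
  as.integer(v) + 1L
}
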