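# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. All randomised operations in the package route through this so
# results are pure functions of their `seed` argument.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive per-trial seeds from a base seed, kept inside 32-bit range
# (double arithmetic avoids integer overflow before the modulus).
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 99991 * seq_len(n)) %% 2147483647)
}
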