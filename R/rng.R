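# Seed plumbing: one root seed, deterministic child streams per operation so
# adding operations never perturbs existing draws.

# deterministic 31-bit child seed from (root seed, stream key)
child_seed <- function(seed, key) {
  x <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(key))) {
    x <- (x * 69069 + ch) %% 2147483647
  }
  as.integer(x)
}

# evaluate `code` under a local RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
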