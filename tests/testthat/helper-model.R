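# Shared fixtures and independent oracles used across the test files.

cfg5 <- model_config(5)
presets <- variant_preset()

# Brute-force Polya urn oracle: exhaustively enumerates every sequence of
# replication draws and accumulates the probability of each final variant-1
# copy number.  Exponential in the number of additions, so only usable for
# tiny targets -- which is exactly why it is an independent check on the
# closed-form replication pmf.
urn_brute_force <- function(i1, i2, n_c) {
  target <- 2L * n_c
  acc <- numeric(target + 1L)
  recurse <- function(c1, c2, p) {
    if (c1 + c2 == target) {
      acc[c1 + 1L] <<- acc[c1 + 1L] + p
      return(invisible(NULL))
    }
    tot <- c1 + c2
    if (c1 > 0L) recurse(c1 + 1L, c2, p * c1 / tot)
    if (c2 > 0L) recurse(c1, c2 + 1L, p * c2 / tot)
  }
  recurse(i1, i2, 1)
  acc
}

# Probability table as a named lookup: prob of a given (a, b) row.
pmf_prob <- function(tab, a, b) {
  hit <- tab$prob[tab[[1L]] == a & tab[[2L]] == b]
  if (length(hit)) sum(hit) else 0
}
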