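# Shared helpers: independent brute-force oracles and generators.

# bits of 0-based row index r, first variable most significant
row_bits <- function(r, n) (r %/% 2^((n - 1):0)) %% 2

# Independent enumeration oracle for the stochastic function: loop over all
# rows, multiply per-variable Bernoulli factors by hand.  Deliberately written
# as a plain double loop, sharing no code with the package internals.
brute_stoch <- function(tt, x) {
  x <- x[tt$vars]
  total <- 0
  for (r in 0:(2^tt$n - 1)) {
    if (tt$outputs[r + 1] == 1) {
      bits <- row_bits(r, tt$n)
      p <- 1
      for (i in seq_len(tt$n)) p <- p * (if (bits[i] == 1) x[[i]] else 1 - x[[i]])
      total <- total + p
    }
  }
  total
}

random_table <- function(n, seed) {
  outs <- stochcrn:::with_seed(seed, sample(0:1, 2^n, replace = TRUE))
  truth_table(outs, name = "F")
}

random_assignment <- function(vars, seed) {
  stochcrn:::with_seed(seed, setNames(runif(length(vars)), vars))
}
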