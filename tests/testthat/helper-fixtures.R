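# Small fixtures shared across test files; everything is generated in code.

# a short, well-behaved profile on a coarse grid
toy_profile <- function(n = 24, sigma = FALSE) {
  q <- seq(0.2, 2, length.out = n)
  i <- 1 / (1 + q^2)
  saxs_profile(q, i, if (sigma) 0.05 * i else NULL, label = "toy")
}

# the reference 60 mol % composite used throughout
model60 <- function() reference_model(60)

# random valid GGP parameter draws for property tests
random_ggp <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- runif(1, 0, 2.5)
    d <- s + runif(1, 0.3, 4.5 - s)
    ggp_params(i0 = 10^runif(1, -1, 2), rg = runif(1, 0.5, 20), d = d, s = s)
  })
}

expect_rel_equal <- function(actual, expected, rtol) {
  denom <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / denom), rtol)
}
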