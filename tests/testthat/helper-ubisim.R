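# Shared fixtures: small configurations and populations built in code.

tiny_config <- function(n = 500L) default_generator_config(n)

tiny_population <- function(n = 500L, seed = 42L) {
  generate_population(tiny_config(n), seed)
}

scenarios4 <- function() default_scenarios()

# Brute-force O(n^2) Gini, the independent oracle for gini().
gini_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(abs(x[i] - x))
  s / (2 * n^2 * mean(x))
}

# Independent weighted-least-squares fit via explicit normal equations,
# the oracle for rii_sii().
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  unname(solve(A, b)[, 1])
}
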