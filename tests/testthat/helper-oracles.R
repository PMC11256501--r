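## Independent oracles used across the suite. These deliberately avoid the
## code paths of the functions they check.

## Closed-form simple linear regression via the 2x2 normal equations.
ols_oracle <- function(x, y) {
  A <- matrix(c(length(x), sum(x), sum(x), sum(x^2)), 2L, 2L)
  b <- c(sum(y), sum(x * y))
  beta <- solve(A, b)
  list(intercept = beta[1L], slope = beta[2L])
}

## Exact one-sided binomial tail P(Y >= y | n, p) by direct enumeration of
## the probability mass terms (log-scale binomial coefficients).
binom_tail_oracle <- function(y, n, p) {
  if (y > n) return(0)
  k <- y:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

## CLAM labels by brute force from the exact tails.
clam_oracle <- function(yA, yB, alpha = 0.05, pi = 2 / 3,
                        coverage_limit = 10) {
  n <- yA + yB
  if (n < coverage_limit) return("too_rare")
  if (binom_tail_oracle(yA, n, pi) <= alpha) return("specialist_A")
  if (binom_tail_oracle(yB, n, pi) <= alpha) return("specialist_B")
  "generalist"
}

## Default-condition chamber truth with the transient switched off, for
## noiseless recovery checks.
noiseless_truth <- function(true_flux) {
  chamber_truth(true_flux = true_flux, transient_amplitude = 0,
                noise_sd = 0)
}
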