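# Shared fixtures, built in code.

# A modest two-component mixture on S_3 used across kernel and EM tests.
test_mixture_k2 <- function() {
  ssd_mixture(c(0.6, 0.4), list(
    ssd_params(c(5, 2, 3), c(0.3, 0.3, 0.4), 1.3),
    ssd_params(c(2, 6, 2), c(0.4, 0.4, 0.2), 0.9)))
}

# Independent log-density oracles (hand-coded closed forms).
oracle_log_dirichlet <- function(y, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(y))
}

oracle_log_scaled_dirichlet <- function(y, alpha, beta) {
  ap <- sum(alpha)
  lgamma(ap) - sum(lgamma(alpha)) - sum(alpha * log(beta)) +
    sum((alpha - 1) * log(y)) - ap * log(sum(y / beta))
}

# 2x2 checkerboard image of a given size.
checkerboard <- function(n) outer(1:n, 1:n, function(i, j) (i + j) %% 2)
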