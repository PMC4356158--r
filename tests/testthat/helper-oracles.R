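# Independent oracles used across the suite.  These deliberately avoid
# the package's genotype-class machinery so they can act as brute-force
# cross-checks.

# Naive per-individual Wright-Fisher simulator under the
# diminishing-effects model: every individual is its own fitness value.
naive_individual_run <- function(N, T, mu, alpha0, g, w0) {
  w <- rep(w0, N)
  for (t in seq_len(T)) {
    w <- w[sample.int(N, N, replace = TRUE, prob = w)]
    mut <- which(stats::runif(N) < mu)
    if (length(mut)) {
      s <- stats::rexp(length(mut), rate = alpha0 * w[mut]^g)
      w[mut] <- w[mut] * (1 + s)
    }
  }
  mean(w)
}

# Closed-form expected fitness of an FGM mutant: for z' = z + d with
# d ~ N(0, sigma^2 I_n) and w(z) = exp(-||z||^2 / 2),
# E[w(z')] = (1 + sigma^2)^(-n/2) * exp(-||z||^2 / (2 (1 + sigma^2))).
fgm_expected_mutant_fitness <- function(z, sigma) {
  n <- length(z)
  (1 + sigma^2)^(-n / 2) * exp(-sum(z^2) / (2 * (1 + sigma^2)))
}

# Geometric-series partial sum oracle for the trajectory forecast:
# cumulative gain after t intervals whose per-interval gains decay
# geometrically by (1 - beta).
geometric_cumulative_gain <- function(beta, first_gain, t) {
  if (t == 0) return(0)
  sum(first_gain * (1 - beta)^(seq_len(t) - 1))
}

# Exact points on the log-log law ln y = a + b ln(-x).
powerlaw_points <- function(x, a, b) {
  data.frame(genotype_id = sprintf("p%02d", seq_along(x)),
             x = x, y = exp(a) * (-x)^b,
             reference_flag = FALSE)
}
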