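# Independent oracles shared across tests.

# Closed-form pmf of the rounded, zero-truncated Gaussian ring offset:
# P(k) proportional to Phi(k + 0.5, sd) - Phi(k - 0.5, sd), k != 0.
oracle_offset_pmf <- function(k, sigma) {
  stopifnot(all(k != 0))
  p <- pnorm(k + 0.5, sd = sigma) - pnorm(k - 0.5, sd = sigma)
  p0 <- pnorm(0.5, sd = sigma) - pnorm(-0.5, sd = sigma)
  p / (1 - p0)
}

# Frequency check: is the observed proportion within `k` standard errors
# of the expected probability?
expect_freq <- function(observed_count, n, p, k = 4) {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(observed_count / n - p), k * se + 1e-12)
}

# Rebuild the config of one replicate of a single-cell grid, the way the
# sweep driver derives it.
cell_config_for_test <- function(grid, replicate) {
  row <- grid$cells[1, ]
  simulation_config(
    payoff_bias = row$payoff_bias, learner_type = row$learner_type,
    population_size = row$population_size, error_rate = grid$error_rate,
    pool_size = grid$pool_size,
    structure_sigma = if (is.na(row$sigma)) NULL else row$sigma,
    n_steps = grid$n_steps, payoff_rate = grid$payoff_rate,
    seed = derive_seed(grid$base_seed, 1, replicate)
  )
}

# Map a model index drawn for focal agent i on an n-ring back to a signed
# offset in (-n/2, n/2].
ring_offset <- function(j, i, n) {
  d <- (j - i) %% n
  ifelse(d > n / 2, d - n, d)
}
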