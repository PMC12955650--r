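# Independent oracles and fixture builders used across the test files.

# Exact model rating table: expected cell counts (rounded) for a total of
# `n_per_class` trials in each stimulus class, computed straight from the
# Gaussian CDF rather than via cell_probabilities().
model_table <- function(mu, sigma, criteria, n_per_class, pad = TRUE) {
  cuts <- c(-Inf, criteria, Inf)
  absent <- rev(diff(pnorm(cuts)))
  present <- rev(diff(pnorm(cuts, mu, sigma)))
  freq <- round(rbind(absent, present) * n_per_class)
  tab <- rating_table(freq, padded = FALSE)
  if (pad) pad_table(tab) else tab
}

# Random multinomial rating table with n rating levels.
random_table <- function(n_levels = 2L, n_per_class = 200L) {
  k <- 2L * n_levels
  freq <- rbind(as.vector(rmultinom(1, n_per_class, prop.table(runif(k) + 0.2))),
                as.vector(rmultinom(1, n_per_class, prop.table(runif(k) + 0.2))))
  rating_table(freq, padded = FALSE)
}

# Brute-force grid-search oracle for the maximized log-likelihood: mu and
# sigma grids crossed with a shared shift applied to the initializer's
# criteria. Any MLE worth its name must reach at least this value.
grid_loglik_oracle <- function(table, n_grid = 21L) {
  base <- initialize_params(table)$criteria
  mus <- seq(-1, 4, length.out = n_grid)
  sigmas <- seq(0.4, 3, length.out = n_grid)
  shifts <- seq(-1, 1, length.out = n_grid)
  best <- -Inf
  for (m in mus) for (s in sigmas) for (sh in shifts) {
    ll <- suppressWarnings(
      uvsdt_loglik(table, uvsdt_params(m, s, base + sh)))
    if (ll > best) best <- ll
  }
  best
}

# Model-implied hit/FA rates at a single criterion, via the Gaussian CDF.
model_rates <- function(mu, sigma, k) {
  list(fa = 1 - pnorm(k), hit = 1 - pnorm((k - mu) / sigma))
}
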