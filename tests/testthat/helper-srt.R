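# Shared fixtures and independent oracles for the test suite.

# Noise-free simulation configuration: closed-form trend only.
noiseless_sim <- function(...) {
  sim_config(
    noise_sigma = 1e-12, noise_tau = 0, outlier_rate = 0,
    general_practice_rate = 0, ...
  )
}

# Independent OLS oracle via the normal equations (never uses lm()).
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

quiet_trim <- function(...) {
  suppressWarnings(suppressMessages(trim_rts(...)))
}

quiet_summary <- function(...) {
  suppressMessages(learning_summary(...))
}

# Pooled empirical transition counts over many seeded blocks.
empirical_transitions <- function(gen, seeds) {
  counts <- matrix(0, 4, 4)
  for (s in seeds) {
    b <- gen(s)
    counts <- counts + table(
      factor(b[-length(b)], levels = 1:4),
      factor(b[-1], levels = 1:4)
    )
  }
  counts
}
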