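# Independent oracles used across the suite. These deliberately re-derive
# quantities in a single expression with different algebra than the
# package code (power laws instead of 10^(a*log10+...), etc.) so agreement
# is evidence, not tautology.

# Single-expression re-evaluation of the full migration model.
table1_oracle <- function(t, D, K, d, v_p, v_f) {
  a <- (1 / K) * (v_f / v_p)
  td <- (d^2 / D) *
    (if (a > 0.2) 0.3552 / (1 + 85.88 * a^(-3.506 / log(10))) else 0.0085 * a^(4.458 / log(10)))
  fts <- (2 / d) * sqrt(D * t / pi)
  if (t <= td) return(fts)
  ftd <- (2 / d) * sqrt(D * td / pi)
  plateau <- a / (1 + a)
  A <- min(max(0.8 * a^0.12, 0.7), 1)
  B <- min(max(0.5 * a^0.22, 0.3), 0.9)
  x3 <- 0.08 * a^0.7
  C3 <- if (x3 < 0.3) 0.004 else if (x3 > 1) 1 else x3
  beta <- (1 / d) * sqrt(D / (pi * td) * (plateau - ftd))
  dt <- t - td
  min(plateau,
      ftd + (plateau - ftd) *
        (A * (1 - exp(-B * beta * dt)) + (1 - A) * (1 - exp(-C3 * beta * dt))))
}

# Random migration-model parameter draws spanning realistic product ranges.
random_migration_inputs <- function(n, seed) {
  set.seed(seed)
  data.frame(
    t = 10^runif(n, 0, 6),
    D = 10^runif(n, -14, -7),
    K = 10^runif(n, -2, 6),
    d = runif(n, 0.05, 0.5),
    v_p = runif(n, 1, 100),
    v_f = runif(n, 1, 100)
  )
}

# Synthetic regression fixture drawn from the published three-predictor
# model plus gaussian log-noise, with molar-mass and partition-coefficient
# decoy columns carrying no additional signal.
gen_eq5_data <- function(n, seed, noise_sd = 0.3) {
  set.seed(seed)
  log10_dp <- runif(n, -14, -7)
  log10_c0 <- runif(n, 1, 5)
  log10_kow <- runif(n, 2, 10)
  log10_mw <- runif(n, 2, 3)
  log10_kms <- 0.6 * log10_kow + rnorm(n, 0, 0.5)
  y <- 3.23 + 0.73 * log10_dp + 0.92 * log10_c0 - 0.06 * log10_kow +
    rnorm(n, 0, noise_sd)
  data.frame(log10_rate = y, log10_dp = log10_dp, log10_c0 = log10_c0,
             log10_kow = log10_kow, log10_mw = log10_mw, log10_kms = log10_kms)
}

# Small noiseless synthetic dataset written to a temp CSV; returns the path.
write_noiseless_dataset <- function(n = 40, seed = 11) {
  ds <- generate_synthetic_dataset(
    synthetic_config(n_observations = n, log10_noise_sd = 0), seed = seed)
  path <- tempfile(fileext = ".csv")
  write_migration_dataset(ds, path)
  path
}
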