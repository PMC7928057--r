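# Independent oracles used across test files.

# Pearson r written out from the definition, independent of stats::cor.
pearson_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Upper-tail probability of the t distribution by numeric integration of
# the density written from its closed form (no call to pt/dt).
t_upper_tail_brute <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  integrate(dens, t, Inf, rel.tol = 1e-10)$value
}

# A noiseless device configuration shared by many tests.
quiet_config <- function(...) control_config(noise_sd = 0, ...)

# Deterministic response table with exact per-lag counts of 1s.
table_from_counts <- function(lags, k, n = 15, participant = 1) {
  rows <- purrr::map2_dfr(lags, k, function(lag, ones) {
    tibble::tibble(lag_ms = lag,
                   response = c(rep(1L, ones), rep(0L, n - ones)))
  })
  tibble::tibble(participant_id = participant,
                 trial_id = seq_len(nrow(rows)),
                 lag_ms = rows$lag_ms, response = rows$response)
}
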