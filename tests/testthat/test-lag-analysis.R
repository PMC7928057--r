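test_that("upsampling preserves constants, the peak and its location", {
  const <- force_trace(rep(1.5, 30), 100)
  up <- upsample_trace(const)
  expect_equal(trace_sample_rate(up), 1000)
  expect_true(all(abs(up$force - 1.5) < 1e-12))

  # 100 Hz pulse -> 1000 Hz: peak location within 1 ms of analytic T/2
  spec <- pulse_spec(sample_rate = 100)
  up2 <- upsample_trace(make_pulse(spec))
  t_peak <- up2$time[which.max(up2$force)]
  expect_lt(abs(t_peak - (spec$pre_silence + 1 / 12)), 1e-3 + 1e-9)
  # peak amplitude preserved within 2 percent for this band-limited pulse
  expect_lt(abs(max(up2$force) - 2) / 2, 0.02)
  # upsampling factor 10: ten times as many intervals
  expect_equal(round((nrow(up2) - 1) / (nrow(make_pulse(spec)) - 1)), 10)
  expect_error(upsample_trace(make_pulse(spec), target_rate = 10), "below")
})

test_that("onset detection crosses 10 percent of the trace's own maximum", {
  # unit step: first exceedance is the step itself
  step <- force_trace(c(rep(0, 100), rep(1, 50)), 1000)
  expect_equal(detect_onset(step)$onset_time, 0.1)
  expect_equal(detect_onset(step)$threshold_level, 0.1)

  # raised-cosine pulse: crossing of the closed form at
  # (1 - cos(2 pi f t))/2 = 0.1, via a root-finding oracle
  spec <- pulse_spec(sample_rate = 1000)
  t_star <- uniroot(function(t) (1 - cos(2 * pi * 6 * t)) / 2 - 0.1,
                    c(0, 1 / 12), tol = 1e-12)$root
  onset <- detect_onset(make_pulse(spec))$onset_time
  expect_lt(abs(onset - (spec$pre_silence + t_star)), 1e-3 + 1e-9)

  # relative threshold: invariant to positive rescaling
  tr <- make_pulse(spec)
  scaled <- force_trace(tr$force * 7.3, 1000)
  expect_equal(detect_onset(scaled)$onset_time, onset)

  # equivariant to time shift
  shifted <- force_trace(tr$force, 1000, t0 = 0.25)
  expect_equal(detect_onset(shifted)$onset_time, onset + 0.25)

  expect_error(detect_onset(force_trace(numeric(10), 100)), "onset")
})

test_that("per-trial lags recover commanded lags through the full pipeline", {
  for (lag in c(40, -120)) {
    rec <- simulate_trial(make_lagged_pair(pulse_spec(), lag),
                          config = quiet_config())
    expect_lt(abs(trial_lag(rec, "target") - lag), 1)
    expect_lt(abs(trial_lag(rec, "measured") - lag), 1)
  }
  # identical channels give zero lag
  z <- make_pulse(pulse_spec())
  rec0 <- simulate_trial(list(vertical = z, horizontal = z, lag_ms = 0),
                         config = quiet_config())
  expect_equal(trial_lag(rec0, "measured"), 0)
})

test_that("condition means and standard errors follow the textbook formulas", {
  same <- tibble::tibble(lag_ms = 40, measured_lag_ms = rep(40, 15))
  out <- condition_means(same)
  expect_equal(out$mean_lag_ms, 40)
  expect_equal(out$se_lag_ms, 0)

  three <- tibble::tibble(lag_ms = 0, measured_lag_ms = c(39, 40, 41))
  out3 <- condition_means(three)
  expect_equal(out3$mean_lag_ms, 40)
  expect_equal(out3$se_lag_ms, 1 / sqrt(3))

  full <- tidyr::expand_grid(lag_ms = design_lags(), rep = 1:2) |>
    dplyr::mutate(measured_lag_ms = lag_ms)
  expect_equal(nrow(condition_means(full, design_lags())), 14)
  expect_error(condition_means(three, expected_lags = c(0, 10)), "10")
})

test_that("the Pearson correlation matches the brute-force formula", {
  x <- as.numeric(design_lags())
  expect_equal(correlate_lags(x, x)$r, 1)
  expect_equal(correlate_lags(x, -x)$r, -1)

  set.seed(42)
  y <- x + rnorm(14, 0, 5)
  res <- correlate_lags(x, y)
  expect_equal(res$r, pearson_brute(x, y), tolerance = 1e-14)
  # regression line agrees with closed-form least squares
  expect_equal(res$slope,
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
               tolerance = 1e-12)
  expect_error(correlate_lags(x, rep(1, 14)), "variance")
  expect_error(correlate_lags(1:2, 1:2), "at least 3")
})

test_that("sensing noise inflates lag variability, not deflates it", {
  pair <- make_lagged_pair(pulse_spec(), 40)
  lag_sd <- function(noise_sd, seeds) {
    lags <- vapply(seeds, function(s) {
      rec <- simulate_trial(pair, config = control_config(noise_sd = noise_sd,
                                                          seed = s))
      trial_lag(rec, "measured")
    }, 0)
    sd(lags)
  }
  seeds <- 1:100
  expect_gt(lag_sd(0.03, seeds), lag_sd(0.005, seeds))
})

test_that("analyze_lags assembles trial lags, condition summary and correlation", {
  sched <- schedule_trials(reps = 2, seed = 3)
  recs <- simulate_recording_set(sched, config = quiet_config())
  res <- analyze_lags(recs)
  expect_equal(nrow(res$trial_lags), nrow(sched))
  expect_equal(nrow(res$condition_summary), 14)
  expect_gte(res$correlation$r, 0.999)
  # per-trial variant uses all trials
  res_pt <- analyze_lags(recs, per_trial = TRUE)
  expect_equal(nrow(res_pt$correlation$data), nrow(sched))
  expect_gte(res_pt$correlation$r, 0.999)
  # tidiers expose the summary and the correlation
  expect_equal(nrow(tidy(res)), 14)
  expect_named(glance(res), c("r", "p_value", "df", "slope", "intercept"))
})
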