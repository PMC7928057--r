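#' Upsample a force trace by linear interpolation and smoothing
#'
#' Linearly interpolates the trace onto a `target_rate` grid (default
#' 1000 Hz, a factor 10 from the 100 Hz control loop) and applies a
#' zero-phase moving-average smoother with reflected boundaries. The
#' default 11-sample (11 ms) window suppresses sensing noise while moving
#' the 10-percent onset of the 6 Hz pulse by less than 1 ms.
#'
#' @param trace A [force_trace()].
#' @param target_rate Output rate in Hz; must be >= the input rate.
#' @param smooth_window Odd moving-average length in output samples;
#'   `1` disables smoothing.
#' @return A [force_trace()] at `target_rate` spanning the same interval.
#' @export
upsample_trace <- function(trace, target_rate = 1000, smooth_window = 11) {
  trace <- as_force_trace(trace)
  sr <- trace_sample_rate(trace)
  if (target_rate < sr) {
    abort(sprintf("target_rate (%g) below input rate (%g Hz).",
                  target_rate, sr))
  }
  check_number(smooth_window, "smooth_window", lower = 1)
  if (smooth_window %% 2 != 1) abort("`smooth_window` must be odd.")
  t_new <- seq(trace$time[[1]], trace$time[[nrow(trace)]], by = 1 / target_rate)
  y <- approx(trace$time, trace$force, xout = t_new, rule = 2)$y
  if (smooth_window > 1) {
    half <- (smooth_window - 1) / 2
    # reflect ends so the zero-phase average keeps endpoints unbiased
    padded <- c(rev(y[2:(half + 1)]), y, rev(y[(length(y) - half):(length(y) - 1)]))
    sm <- stats::filter(padded, rep(1 / smooth_window, smooth_window),
                        sides = 2)
    y <- as.numeric(sm[(half + 1):(half + length(y))])
  }
  force_trace(y, sample_rate = target_rate, t0 = trace$time[[1]])
}

#' Detect signal onset at 10 percent of maximum amplitude
#'
#' The onset is the time of the first sample strictly exceeding
#' `threshold_frac` of the trace's own maximum. The threshold is relative,
#' so onset time is invariant to positive rescaling of the trace.
#'
#' @param trace A [force_trace()].
#' @param threshold_frac Fraction of the maximum (default 0.10).
#' @return A list of class `onset_result` with `onset_time` (s),
#'   `threshold_level` (N) and `max_amplitude` (N).
#' @examples
#' detect_onset(upsample_trace(make_pulse()))$onset_time
#' @export
detect_onset <- function(trace, threshold_frac = 0.10) {
  trace <- as_force_trace(trace)
  check_number(threshold_frac, "threshold_frac",
               lower = .Machine$double.eps, upper = 1)
  m <- max(trace$force)
  if (m <= 0) abort("trace has no positive excursion: onset undefined.")
  thr <- threshold_frac * m
  idx <- which(trace$force > thr)[1]
  if (is.na(idx)) abort("no sample exceeds the onset threshold.")
  structure(
    list(onset_time = trace$time[[idx]], threshold_level = thr,
         max_amplitude = m),
    class = "onset_result"
  )
}

#' Onset time-lag between the two motor channels of one trial
#'
#' Upsamples both channels to `target_rate`, detects their 10-percent
#' onsets and returns `onset(horizontal) - onset(vertical)` in ms, so a
#' positive lag means the vertical channel led — matching the sign
#' convention of the commanded lags.
#'
#' @param rec A `trial_recording`.
#' @param which `"target"` (commanded input stage) or `"measured"` (motor
#'   current stage).
#' @inheritParams upsample_trace
#' @inheritParams detect_onset
#' @return Lag in ms (scalar).
#' @export
trial_lag <- function(rec, which = c("target", "measured"),
                      target_rate = 1000, smooth_window = 11,
                      threshold_frac = 0.10) {
  stopifnot(inherits(rec, "trial_recording"))
  which <- match.arg(which)
  v <- if (which == "target") rec$target_v else rec$measured_v
  h <- if (which == "target") rec$target_h else rec$measured_h
  ov <- detect_onset(upsample_trace(v, target_rate, smooth_window),
                     threshold_frac)
  oh <- detect_onset(upsample_trace(h, target_rate, smooth_window),
                     threshold_frac)
  1000 * (oh$onset_time - ov$onset_time)
}

#' Per-condition mean and standard error of measured lags
#'
#' Averages per-trial lags within each commanded-lag condition, as done
#' when verifying the device: 15 trials per condition, mean +/- SE
#' (sd / sqrt(n)) per condition, ordered by commanded lag.
#'
#' @param trials A data frame with columns `lag_ms` (commanded condition)
#'   and `measured_lag_ms` (per-trial estimate).
#' @param expected_lags Optional vector of conditions that must all be
#'   present (e.g. [design_lags()]); a missing one raises an error naming it.
#' @return A tibble with `lag_ms`, `n`, `mean_lag_ms`, `se_lag_ms`.
#' @export
condition_means <- function(trials, expected_lags = NULL) {
  if (!all(c("lag_ms", "measured_lag_ms") %in% names(trials))) {
    abort("`trials` needs columns `lag_ms` and `measured_lag_ms`.")
  }
  if (!is.null(expected_lags)) {
    missing <- setdiff(expected_lags, unique(trials$lag_ms))
    if (length(missing)) {
      abort(paste0("no trials for lag condition(s): ",
                   paste(missing, collapse = ", "), " ms."))
    }
  }
  counts <- dplyr::count(trials, .data$lag_ms)
  if (any(counts$n < 2)) {
    abort("every lag condition needs at least 2 trials for a standard error.")
  }
  trials |>
    dplyr::group_by(.data$lag_ms) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_lag_ms = mean(.data$measured_lag_ms),
      se_lag_ms = sd(.data$measured_lag_ms) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag_ms)
}

#' Correlate commanded and delivered time-lags
#'
#' Pearson product-moment correlation between the intended lags (target
#' input stage) and the delivered lags (motor stage), with the least-squares
#' line for the parity plot. Used to verify that the device realises the
#' commanded lag structure (the physical prototype reached r = 0.9986).
#'
#' @param target Commanded lags, ms (length >= 3).
#' @param actual Delivered lags (same length), typically condition means.
#' @param actual_se Optional standard errors carried through for plotting.
#' @return A list of class `lag_correlation`: `r`, `p`, `df`, `slope`,
#'   `intercept`, and tibble `data`.
#' @export
correlate_lags <- function(target, actual, actual_se = NULL) {
  if (length(target) != length(actual)) {
    abort("`target` and `actual` must have the same length.")
  }
  if (length(target) < 3L) abort("need at least 3 conditions.")
  if (sd(target) == 0 || sd(actual) == 0) {
    abort("zero variance: correlation undefined.")
  }
  ct <- cor.test(target, actual, method = "pearson")
  line <- lm(actual ~ target)
  structure(
    list(r = unname(ct$estimate), p = ct$p.value,
         df = unname(ct$parameter),
         slope = unname(coef(line)[2]), intercept = unname(coef(line)[1]),
         data = tibble(target_lag_ms = target, actual_lag_ms = actual,
                       actual_se_ms = actual_se %||% NA_real_)),
    class = "lag_correlation"
  )
}

#' @export
print.lag_correlation <- function(x, ...) {
  cat(sprintf(
    "<lag_correlation: r = %.4f, p = %.3g, n = %d conditions, slope = %.3f>\n",
    x$r, x$p, nrow(x$data), x$slope))
  invisible(x)
}

#' Run the full device-verification lag analysis
#'
#' For every recording: per-trial lags at the target and measured stages
#' (upsample to 1000 Hz, smooth, 10-percent onsets), then per-condition
#' means and the Pearson correlation of commanded vs delivered lag. The
#' correlation is computed on the condition means, as in the device's
#' published verification; set `per_trial = TRUE` for the 210-point variant.
#'
#' @param recordings A list of `trial_recording`s (see
#'   [simulate_recording_set()]).
#' @param per_trial Correlate per-trial lags instead of condition means.
#' @inheritParams trial_lag
#' @return A list of class `lag_analysis` with tibbles `trial_lags` and
#'   `condition_summary`, and `correlation` (a `lag_correlation`).
#' @export
analyze_lags <- function(recordings, per_trial = FALSE, target_rate = 1000,
                         smooth_window = 11, threshold_frac = 0.10) {
  stopifnot(length(recordings) >= 1)
  trial_lags <- purrr::map_dfr(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    tibble(
      trial_id = i,
      lag_ms = rec$commanded_lag,
      target_lag_ms = trial_lag(rec, "target", target_rate, smooth_window,
                                threshold_frac),
      measured_lag_ms = trial_lag(rec, "measured", target_rate,
                                  smooth_window, threshold_frac)
    )
  })
  summ <- condition_means(trial_lags)
  corr <- if (per_trial) {
    correlate_lags(trial_lags$lag_ms, trial_lags$measured_lag_ms)
  } else {
    correlate_lags(summ$lag_ms, summ$mean_lag_ms, summ$se_lag_ms)
  }
  structure(
    list(trial_lags = trial_lags, condition_summary = summ,
         correlation = corr),
    class = "lag_analysis"
  )
}
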