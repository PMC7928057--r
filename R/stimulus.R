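#' Stimulus pulse specification
#'
#' Describes the single skin-stretch force pulse: a raised-cosine bump
#' `peak * (1 - cos(2*pi*frequency*t)) / 2` lasting one period
#' (`1/frequency`), flanked by silent padding. The default is the 6 Hz,
#' 2 N pulse (about 167 ms long) used for both motor channels; the
#' raised-cosine shape keeps the commanded force non-negative, as required
#' by a wire-and-tab coupling that can only pull the skin.
#'
#' @param frequency Pulse frequency in Hz; pulse duration is `1/frequency`.
#' @param peak Peak force in N.
#' @param sample_rate Sampling rate in Hz; must be at least `2 * frequency`.
#' @param pre_silence,post_silence Zero padding before and after the pulse,
#'   in seconds. The pre-silence must absorb the largest commanded lag.
#'
#' @return A list of class `pulse_spec`.
#' @seealso [make_pulse()], [make_lagged_pair()]
#' @export
pulse_spec <- function(frequency = 6, peak = 2, sample_rate = 100,
                       pre_silence = 0.2, post_silence = 0.3) {
  check_number(frequency, "frequency", lower = .Machine$double.eps)
  check_number(peak, "peak", lower = .Machine$double.eps)
  check_number(sample_rate, "sample_rate", lower = .Machine$double.eps)
  check_number(pre_silence, "pre_silence", lower = 0)
  check_number(post_silence, "post_silence", lower = 0)
  if (sample_rate < 2 * frequency) {
    abort(sprintf(
      "sample_rate (%g Hz) is below the Nyquist limit 2 * frequency = %g Hz.",
      sample_rate, 2 * frequency))
  }
  structure(
    list(frequency = frequency, peak = peak, sample_rate = sample_rate,
         pre_silence = pre_silence, post_silence = post_silence),
    class = "pulse_spec"
  )
}

#' The standard set of signed time-lag conditions
#'
#' Fourteen lags in milliseconds, symmetric about zero with a gap at 0.
#' Positive lags mean the vertical pulse starts before the horizontal one.
#'
#' @return Integer vector of 14 lags (ms).
#' @export
design_lags <- function() {
  c(-120L, -100L, -80L, -60L, -40L, -20L, -10L,
    10L, 20L, 40L, 60L, 80L, 100L, 120L)
}

#' Generate a single force pulse
#'
#' Samples the raised-cosine bump of [pulse_spec()] on the spec's uniform
#' grid: zero during the pre-silence, `peak * (1 - cos(2*pi*f*t))/2` for one
#' period, zero afterwards. The waveform is non-negative with a single
#' maximum equal to `peak` at mid-pulse (up to grid discretisation).
#'
#' @param spec A [pulse_spec()].
#' @return A [force_trace()] at `spec$sample_rate`.
#' @examples
#' tr <- make_pulse(pulse_spec())
#' max(tr$force)
#' @export
make_pulse <- function(spec = pulse_spec()) {
  stopifnot(inherits(spec, "pulse_spec"))
  dur <- 1 / spec$frequency
  total <- spec$pre_silence + dur + spec$post_silence
  n <- floor(total * spec$sample_rate) + 1L
  t <- (seq_len(n) - 1) / spec$sample_rate
  tp <- t - spec$pre_silence
  f <- ifelse(tp >= 0 & tp <= dur,
              spec$peak * (1 - cos(2 * pi * spec$frequency * tp)) / 2,
              0)
  force_trace(pmax(f, 0), sample_rate = spec$sample_rate)
}

#' Generate a lagged vertical/horizontal pulse pair
#'
#' Places two identical pulses on a common time base such that for
#' `lag_ms > 0` the vertical onset precedes the horizontal one by exactly
#' `lag_ms` milliseconds (the field's sign convention: positive = vertical
#' first). Lags are realised as integer sample shifts, so `lag_ms` must be a
#' multiple of the sample interval; at the 100 Hz control rate the design's
#' +/-10 ms conditions are exactly one control-loop sample.
#'
#' @param spec A [pulse_spec()].
#' @param lag_ms Signed lag in ms (vertical onset minus horizontal onset,
#'   negated; positive = vertical earlier).
#' @return A list with `vertical` and `horizontal` [force_trace()]s of equal
#'   length and rate, and the element `lag_ms`.
#' @examples
#' pair <- make_lagged_pair(pulse_spec(), lag_ms = 40)
#' @export
make_lagged_pair <- function(spec = pulse_spec(), lag_ms = 0) {
  check_number(lag_ms, "lag_ms")
  dt_ms <- 1000 / spec$sample_rate
  shift <- lag_ms / dt_ms
  if (abs(shift - round(shift)) > 1e-9) {
    abort(sprintf(
      "lag_ms = %g is not a multiple of the sample interval (%g ms).",
      lag_ms, dt_ms))
  }
  shift <- as.integer(round(shift))
  if (abs(lag_ms) / 1000 > spec$pre_silence) {
    abort(sprintf(
      "|lag_ms| = %g ms exceeds the pre-silence padding (%g ms).",
      abs(lag_ms), 1000 * spec$pre_silence))
  }
  base <- make_pulse(spec)
  sr <- spec$sample_rate
  shift_trace <- function(f, k) {
    # positive k delays the pulse by k samples
    if (k == 0) return(f)
    if (k > 0) c(rep(0, k), head(f, -k)) else c(tail(f, k), rep(0, -k))
  }
  # positive lag: vertical first => delay the horizontal channel
  v <- shift_trace(base$force, if (shift < 0) -shift else 0L)
  h <- shift_trace(base$force, if (shift > 0) shift else 0L)
  list(vertical = force_trace(v, sr),
       horizontal = force_trace(h, sr),
       lag_ms = lag_ms)
}

#' Build the pseudo-random trial schedule
#'
#' Repeats each lag condition `reps` times and applies a seeded uniform
#' permutation, reproducing the standard design of 14 lags x 15 repetitions
#' = 210 trials presented in pseudo-random order.
#'
#' @param lags Integer vector of lag conditions in ms
#'   (default [design_lags()]).
#' @param reps Repetitions per lag (default 15).
#' @param seed Integer seed for the permutation.
#' @return A tibble of class `trial_schedule` with columns `trial_id` and
#'   `lag_ms`, and attribute `seed`.
#' @examples
#' sched <- schedule_trials(seed = 1)
#' nrow(sched)  # 210
#' @export
schedule_trials <- function(lags = design_lags(), reps = 15, seed = 1) {
  if (length(lags) < 1L) abort("`lags` must be non-empty.")
  check_number(reps, "reps", lower = 1)
  pool <- rep(as.numeric(lags), each = reps)
  ord <- with_seed(seed, sample.int(length(pool)))
  out <- tibble(trial_id = seq_along(pool), lag_ms = pool[ord])
  attr(out, "seed") <- seed
  class(out) <- c("trial_schedule", class(out))
  out
}
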