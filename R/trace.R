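#' Uniformly sampled force trace
#'
#' A `force_trace` is a tibble with columns `time` (s) and `force` (N),
#' uniformly sampled at `sample_rate` Hz starting at `t0`. It is the unit of
#' exchange between the stimulus generator, the device simulator and the lag
#' analysis: one channel (vertical or horizontal) of commanded or measured
#' force for one trial.
#'
#' @param force Numeric vector of force samples in newtons. All values must
#'   be finite and there must be at least two samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#'
#' @return A tibble of class `force_trace` with columns `time` and `force`
#'   and attributes `sample_rate` and `t0`.
#' @examples
#' tr <- force_trace(c(0, 1, 2, 1, 0), sample_rate = 100)
#' trace_sample_rate(tr)
#' @export
force_trace <- function(force, sample_rate, t0 = 0) {
  if (!is.numeric(force) || length(force) < 2L) {
    abort("`force` must be a numeric vector with at least two samples.")
  }
  if (!all(is.finite(force))) {
    abort("`force` contains non-finite values.")
  }
  check_number(sample_rate, "sample_rate", lower = .Machine$double.eps)
  check_number(t0, "t0")
  out <- tibble(
    time = t0 + (seq_along(force) - 1) / sample_rate,
    force = as.numeric(force)
  )
  attr(out, "sample_rate") <- as.numeric(sample_rate)
  attr(out, "t0") <- as.numeric(t0)
  class(out) <- c("force_trace", class(out))
  out
}

#' @rdname force_trace
#' @param x A `force_trace`.
#' @export
trace_sample_rate <- function(x) {
  sr <- attr(x, "sample_rate")
  if (is.null(sr)) abort("not a force_trace: missing sample_rate attribute.")
  sr
}

#' @rdname force_trace
#' @export
is_force_trace <- function(x) inherits(x, "force_trace")

as_force_trace <- function(df, sample_rate = NULL) {
  if (is_force_trace(df)) return(df)
  if (!all(c("time", "force") %in% names(df))) {
    abort("expected columns `time` and `force`.")
  }
  dt <- diff(df$time)
  if (length(dt) < 1L) abort("trace needs at least two samples.")
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("trace is not uniformly sampled.")
  }
  sr <- sample_rate %||% (1 / mean(dt))
  force_trace(df$force, sample_rate = sr, t0 = df$time[[1]])
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace: %d samples @ %g Hz, t0 = %g s, peak = %.3g N>\n",
              nrow(x), trace_sample_rate(x), attr(x, "t0"), max(x$force)))
  NextMethod()
}

stopifnot_same_grid <- function(a, b, what = "traces") {
  if (abs(trace_sample_rate(a) - trace_sample_rate(b)) > 1e-9) {
    abort(sprintf("%s have different sample rates (%g vs %g Hz).",
                  what, trace_sample_rate(a), trace_sample_rate(b)))
  }
  if (nrow(a) != nrow(b)) {
    abort(sprintf("%s have different lengths (%d vs %d samples).",
                  what, nrow(a), nrow(b)))
  }
  invisible(TRUE)
}
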