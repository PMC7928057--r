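#' Broom-style tidiers for skinstretch result objects
#'
#' `tidy()` returns one row per estimated quantity (or participant);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `psychometric_fit`, `toj_group`, `toj_analysis`,
#'   `lag_correlation` or `lag_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @name skinstretch-tidiers
NULL

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.psychometric_fit <- function(x, ...) {
  tibble(participant_id = as.character(x$participant),
         pse_ms = x$pse, jnd_ms = x$jnd, scale_ms = x$s,
         n_trials = x$n_trials, converged = x$converged,
         separation = x$separation)
}

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::glance
glance.psychometric_fit <- function(x, ...) {
  tibble(fit_mode = x$fit_mode,
         neg_log_likelihood = x$neg_log_likelihood,
         n_trials = x$n_trials, converged = x$converged)
}

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.toj_group <- function(x, ...) {
  tibble(term = c("pse", "jnd"),
         mean_ms = c(x$mean_pse, x$mean_jnd),
         se_ms = c(x$se_pse, x$se_jnd))
}

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::glance
glance.toj_group <- function(x, ...) {
  tibble(t_stat = x$t_stat, df = x$df, p_value = x$p_value,
         tail = x$tail, n = x$n, degenerate = x$degenerate)
}

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.toj_analysis <- function(x, ...) x$participants

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::glance
glance.toj_analysis <- function(x, ...) {
  if (is.null(x$group)) {
    return(tibble(mean_pse_ms = x$participants$pse_ms,
                  mean_jnd_ms = x$participants$jnd_ms,
                  t_stat = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  tibble(mean_pse_ms = x$group$mean_pse, se_pse_ms = x$group$se_pse,
         mean_jnd_ms = x$group$mean_jnd, se_jnd_ms = x$group$se_jnd,
         t_stat = x$group$t_stat, df = x$group$df,
         p_value = x$group$p_value, tail = x$group$tail)
}

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.lag_correlation <- function(x, ...) x$data

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::glance
glance.lag_correlation <- function(x, ...) {
  tibble(r = x$r, p_value = x$p, df = x$df,
         slope = x$slope, intercept = x$intercept)
}

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.lag_analysis <- function(x, ...) x$condition_summary

#' @rdname skinstretch-tidiers
#' @export
#' @exportS3Method generics::glance
glance.lag_analysis <- function(x, ...) glance(x$correlation)

#' @export
print.toj_group <- function(x, ...) {
  cat(sprintf(
    "<toj_group: n = %d, PSE %.2f (SE %.2f) ms, JND %s, t(%d) = %.3f, %s p = %.4f>\n",
    x$n, x$mean_pse, x$se_pse,
    if (is.na(x$mean_jnd)) "-" else
      sprintf("%.2f (SE %.2f) ms", x$mean_jnd, x$se_jnd),
    x$df, x$t_stat, x$tail, x$p_value))
  invisible(x)
}

#' @export
print.toj_analysis <- function(x, ...) {
  cat(sprintf("<toj_analysis (%s): %d participant(s)>\n",
              x$fit_mode, length(x$fits)))
  print(x$participants)
  if (!is.null(x$group)) print(x$group)
  invisible(x)
}
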