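#' Per-lag response proportions for one participant
#'
#' The proportion of "vertical first" responses at each lag, with trial
#' counts — the raw psychometric data points.
#'
#' @param table A response table: columns `participant_id`, `lag_ms`,
#'   `response` (1 = vertical judged first, 0 = horizontal first).
#' @param participant Participant id to select.
#' @return A tibble with `lag_ms`, `n`, `k` (count of 1s), `proportion`.
#' @export
response_proportions <- function(table, participant) {
  check_response_table(table)
  tab <- dplyr::filter(table, .data$participant_id == participant)
  if (nrow(tab) == 0) {
    abort(sprintf("participant '%s' not found in the response table.",
                  as.character(participant)))
  }
  tab |>
    dplyr::group_by(.data$lag_ms) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$response),
                     proportion = mean(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$lag_ms)
}

check_response_table <- function(table) {
  need <- c("participant_id", "lag_ms", "response")
  if (!all(need %in% names(table))) {
    abort(paste0("response table needs columns: ",
                 paste(need, collapse = ", "), "."))
  }
  if (!all(table$response %in% c(0, 1))) {
    abort("`response` must be binary (0/1).")
  }
  invisible(TRUE)
}

logistic_p <- function(lag, mu, s) plogis((lag - mu) / s)

nll_bernoulli <- function(par, lag, y) {
  p <- logistic_p(lag, par[1], par[2])
  eps <- 1e-12
  -sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Fit a logistic psychometric function to TOJ responses
#'
#' Fits `P(vertical first | lag t) = 1 / (1 + exp(-(t - mu)/s))` to one
#' participant's binary responses. The default criterion is maximum
#' likelihood on the raw Bernoulli responses; `fit_mode =
#' "proportions-ls"` instead minimises squared error on the per-lag
#' proportions (the curve "fitted to the distribution of averaged
#' probabilities"). The PSE (50 percent cross-over) is `mu`; the JND —
#' half the lag span between the 25 and 75 percent points — is `s * ln 3`
#' for this symmetric logistic.
#'
#' Optimisation uses deterministic starts (`mu0` = lag whose proportion is
#' nearest 0.5 by linear interpolation, `s0` = lag range / 8) and bounds
#' `s` in `[s_min, s_max]` ms. Complete separation (no overlap between the
#' all-0 and all-1 lag regions) is reported with a warning and the scale
#' pinned near its lower bound, never as a silent success.
#'
#' @inheritParams response_proportions
#' @param fit_mode `"mle"` or `"proportions-ls"`.
#' @param s_min,s_max Bounds on the logistic scale, ms.
#' @return A list of class `psychometric_fit`: `mu`, `s`, `pse`, `jnd`,
#'   `n_trials`, `converged`, `separation`, `neg_log_likelihood`,
#'   `fit_mode`, `participant`, and the per-lag `proportions` tibble.
#' @examples
#' tab <- simulate_responder(responder_params(seed = 7))
#' fit <- fit_psychometric(tab, participant = 1)
#' tidy(fit)
#' @export
fit_psychometric <- function(table, participant,
                             fit_mode = c("mle", "proportions-ls"),
                             s_min = 1, s_max = 500) {
  fit_mode <- match.arg(fit_mode)
  props <- response_proportions(table, participant)
  if (nrow(props) < 4L) {
    abort("need responses at >= 4 distinct lags to fit a psychometric curve.")
  }
  if (all(props$proportion == 0) || all(props$proportion == 1)) {
    abort("both response categories must occur to fit a psychometric curve.")
  }
  tab <- dplyr::filter(table, .data$participant_id == participant)

  # deterministic starts: lag nearest the 50% point by interpolation
  mu0 <- {
    pr <- props$proportion
    if (any(pr >= 0.5) && any(pr <= 0.5)) {
      approx(pr + 1e-9 * seq_along(pr), props$lag_ms, xout = 0.5,
             ties = "ordered", rule = 2)$y
    } else {
      mean(props$lag_ms)
    }
  }
  s0 <- min(max(diff(range(props$lag_ms)) / 8, s_min), s_max)

  objective <- if (fit_mode == "mle") {
    function(par) nll_bernoulli(par, tab$lag_ms, tab$response)
  } else {
    function(par) {
      sum((props$proportion - logistic_p(props$lag_ms, par[1], par[2]))^2)
    }
  }
  opt <- optim(c(mu0, s0), objective, method = "L-BFGS-B",
               lower = c(min(props$lag_ms) - 500, s_min),
               upper = c(max(props$lag_ms) + 500, s_max),
               control = list(factr = 1e-8 / .Machine$double.eps))
  mu <- opt$par[1]
  s <- opt$par[2]

  # complete separation: all 0s strictly below all 1s with no mixed lag
  mixed <- props$proportion > 0 & props$proportion < 1
  separation <- !any(mixed) &&
    max(props$lag_ms[props$proportion == 0]) <
      min(props$lag_ms[props$proportion == 1])
  if (separation) {
    warn(paste("complete separation: responses are perfectly ordered;",
               "the fitted scale is pinned near its lower bound."))
  }
  structure(
    list(mu = mu, s = s, pse = mu, jnd = s * log(3),
         n_trials = nrow(tab), converged = opt$convergence == 0,
         separation = separation,
         neg_log_likelihood = nll_bernoulli(c(mu, s), tab$lag_ms,
                                            tab$response),
         fit_mode = fit_mode, participant = participant,
         proportions = props),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit (%s): participant %s, PSE = %.2f ms, JND = %.2f ms, %d trials%s>\n",
    x$fit_mode, as.character(x$participant), x$pse, x$jnd, x$n_trials,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' JND by numeric inversion of the fitted curve
#'
#' Computes half the lag difference between the 25 and 75 percent points
#' of the fitted psychometric function by root finding on the curve. For
#' the symmetric logistic this equals `s * ln 3` analytically; the numeric
#' route exists to validate that identity and to support non-logistic
#' extensions.
#'
#' @param fit A converged `psychometric_fit`.
#' @return JND in ms.
#' @export
jnd_from_curve <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) abort("fit did not converge: JND undefined.")
  invert <- function(p) {
    span <- max(1e4, 100 * fit$s)
    uniroot(function(t) logistic_p(t, fit$mu, fit$s) - p,
            interval = fit$mu + c(-span, span), tol = 1e-10)$root
  }
  (invert(0.75) - invert(0.25)) / 2
}

#' Group-level inference on PSE values
#'
#' One-sample t-test of the per-participant cross-over points against zero
#' lag, with the tail stated explicitly (no default direction), plus group
#' summaries of PSE and JND. The degenerate all-equal-zero case (sd = 0,
#' mean = 0) is reported with `t = 0`, `p = 0.5` and a flag rather than
#' `NaN`.
#'
#' @param pse_values Per-participant PSE estimates, ms (n >= 2).
#' @param tail `"less"`, `"greater"` or `"two-sided"` — the alternative
#'   for the test of mean PSE against 0.
#' @param jnd_values Optional per-participant JNDs, summarised alongside.
#' @return A list of class `toj_group`: `mean_pse`, `se_pse`, `mean_jnd`,
#'   `se_jnd`, `t_stat`, `df`, `p_value`, `tail`, `n`, `degenerate`.
#' @export
group_inference <- function(pse_values, tail = c("less", "greater",
                                                 "two-sided"),
                            jnd_values = NULL) {
  tail <- match.arg(tail)
  n <- length(pse_values)
  if (n < 2L) abort("group inference needs at least 2 participants.")
  if (!all(is.finite(pse_values))) abort("PSE values must be finite.")
  degenerate <- sd(pse_values) == 0
  if (degenerate) {
    if (mean(pse_values) != 0) {
      abort("all PSE values identical and non-zero: t statistic unbounded.")
    }
    t_stat <- 0; p <- 0.5
  } else {
    alt <- if (tail == "two-sided") "two.sided" else tail
    tt <- t.test(pse_values, mu = 0, alternative = alt)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(per_participant_pse = pse_values,
         per_participant_jnd = jnd_values,
         mean_pse = mean(pse_values),
         se_pse = if (degenerate) 0 else sd(pse_values) / sqrt(n),
         mean_jnd = if (is.null(jnd_values)) NA_real_ else mean(jnd_values),
         se_jnd = if (is.null(jnd_values)) NA_real_ else
           sd(jnd_values) / sqrt(length(jnd_values)),
         t_stat = t_stat, df = n - 1, p_value = p, tail = tail, n = n,
         degenerate = degenerate),
    class = "toj_group"
  )
}

#' One-sample t-test from printed summary statistics
#'
#' Recomputes the group test when only the published mean, standard error
#' and sample size are available: `t = mean / se` with `df = n - 1` and the
#' tail probability from the t distribution.
#'
#' @param mean Group mean, same units as the tested quantity.
#' @param se Standard error of the mean.
#' @param n Number of participants.
#' @inheritParams group_inference
#' @return A tibble with `t_stat`, `df`, `p_value`, `tail`.
#' @examples
#' t_test_from_summary(-18.37, 7.21, n = 3, tail = "less")
#' @export
t_test_from_summary <- function(mean, se, n,
                                tail = c("less", "greater", "two-sided")) {
  tail <- match.arg(tail)
  check_number(se, "se", lower = .Machine$double.eps)
  check_number(n, "n", lower = 2)
  t_stat <- mean / se
  df <- n - 1
  p <- switch(tail,
              less = pt(t_stat, df),
              greater = pt(t_stat, df, lower.tail = FALSE),
              `two-sided` = 2 * pt(-abs(t_stat), df))
  tibble(t_stat = t_stat, df = df, p_value = p, tail = tail)
}

#' Pooled psychometric data across participants
#'
#' Cross-participant mean and SE of the per-lag proportions, plus a curve
#' fitted to the pooled responses — the group-level picture of the TOJ
#' data. With a single participant the SE is reported as `NA`.
#'
#' @inheritParams response_proportions
#' @inheritParams fit_psychometric
#' @return A list of class `pooled_curve` with tibble `pooled` (`lag_ms`,
#'   `n_participants`, `mean_proportion`, `se_proportion`) and `fit` (a
#'   `psychometric_fit` on the pooled responses, participant id "pooled").
#' @export
pooled_curve <- function(table, fit_mode = c("mle", "proportions-ls")) {
  fit_mode <- match.arg(fit_mode)
  check_response_table(table)
  per <- table |>
    dplyr::group_by(.data$participant_id, .data$lag_ms) |>
    dplyr::summarise(proportion = mean(.data$response), .groups = "drop")
  pooled <- per |>
    dplyr::group_by(.data$lag_ms) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      mean_proportion = mean(.data$proportion),
      se_proportion = if (dplyr::n() > 1)
        sd(.data$proportion) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag_ms)
  all_tab <- dplyr::mutate(table, participant_id = "pooled")
  fit <- fit_psychometric(all_tab, "pooled", fit_mode = fit_mode)
  structure(list(pooled = pooled, fit = fit), class = "pooled_curve")
}

#' Run the full TOJ analysis over a response table
#'
#' Fits each participant's psychometric function, derives PSE and JND, and
#' performs the group-level one-sample t-test of the cross-over against
#' zero lag.
#'
#' @inheritParams fit_psychometric
#' @inheritParams group_inference
#' @return A list of class `toj_analysis` with `fits` (named list of
#'   `psychometric_fit`s), `participants` (tidy per-participant tibble) and
#'   `group` (a `toj_group`).
#' @export
analyze_toj <- function(table, tail = c("less", "greater", "two-sided"),
                        fit_mode = c("mle", "proportions-ls")) {
  tail <- match.arg(tail)
  fit_mode <- match.arg(fit_mode)
  check_response_table(table)
  ids <- unique(table$participant_id)
  fits <- purrr::map(ids, ~ fit_psychometric(table, .x, fit_mode = fit_mode))
  names(fits) <- as.character(ids)
  participants <- purrr::map_dfr(fits, tidy)
  group <- if (length(ids) >= 2) {
    group_inference(purrr::map_dbl(fits, "pse"), tail = tail,
                    jnd_values = purrr::map_dbl(fits, "jnd"))
  }
  structure(
    list(fits = fits, participants = participants, group = group,
         tail = tail, fit_mode = fit_mode),
    class = "toj_analysis"
  )
}
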