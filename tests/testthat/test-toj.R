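test_that("response proportions are plain per-lag counts", {
  tab <- table_from_counts(design_lags(),
                           k = c(0, 0, 1, 2, 4, 6, 7, 9, 11, 13, 14, 15, 15, 15))
  props <- response_proportions(tab, 1)
  expect_equal(nrow(props), 14)
  expect_equal(props$proportion[props$lag_ms == 10], 9 / 15)
  expect_equal(props$proportion[props$lag_ms == 80], 15 / 15)
  expect_true(all(props$n == 15))
  expect_error(response_proportions(tab, "nobody"), "not found")
})

test_that("the MLE logistic fit agrees with logistic regression", {
  tab <- simulate_responder(responder_params(seed = 31))
  fit <- fit_psychometric(tab, 1)
  g <- stats::glm(response ~ lag_ms, family = stats::binomial, data = tab)
  expect_lt(abs(fit$mu - (-coef(g)[1] / coef(g)[2])), 1e-3)
  expect_lt(abs(fit$s - 1 / coef(g)[2]), 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$pse, fit$mu)
  expect_equal(fit$jnd, fit$s * log(3))
})

test_that("the MLE's likelihood is at least that of the generating parameters", {
  gen <- responder_params(seed = 1)
  nll <- function(mu, s, tab) {
    p <- stats::plogis((tab$lag_ms - mu) / s)
    -sum(tab$response * log(p) + (1 - tab$response) * log(1 - p))
  }
  for (s in c(11, 23, 47)) {
    tab <- simulate_responder(responder_params(seed = s))
    fit <- fit_psychometric(tab, 1)
    expect_lte(fit$neg_log_likelihood, nll(gen$mu, gen$s, tab) + 1e-6)
  }
})

test_that("shifting every lag shifts the PSE and leaves the JND unchanged", {
  tab <- simulate_responder(responder_params(seed = 5))
  fit <- fit_psychometric(tab, 1)
  shifted <- dplyr::mutate(tab, lag_ms = lag_ms + 50)
  fit2 <- fit_psychometric(shifted, 1)
  expect_equal(fit2$pse, fit$pse + 50, tolerance = 1e-6)
  expect_equal(fit2$jnd, fit$jnd, tolerance = 1e-6)
})

test_that("a flat coin responder yields a near-flat fitted curve", {
  # 7 or 8 of 15 at every lag: proportions hug 0.5 with no trend
  tab <- table_from_counts(design_lags(), k = rep(c(7, 8), 7))
  fit <- fit_psychometric(tab, 1)
  expect_gt(fit$s, 100)
})

test_that("complete separation is flagged, not silently absorbed", {
  tab <- table_from_counts(design_lags(),
                           k = c(rep(0, 7), rep(15, 7)))
  expect_warning(fit <- fit_psychometric(tab, 1), "separation")
  expect_true(fit$separation)
  expect_lte(fit$s, 1 + 1e-6)  # pinned at the configured lower bound
})

test_that("degenerate response tables are rejected with useful errors", {
  tab <- table_from_counts(c(-10, 10), k = c(3, 12))
  expect_error(fit_psychometric(tab, 1), "4 distinct lags")
  all_ones <- table_from_counts(design_lags(), k = rep(15, 14))
  expect_error(fit_psychometric(all_ones, 1), "both response categories")
})

test_that("both fitting criteria recover the generating parameters", {
  gen <- responder_params(seed = 60)
  tab <- simulate_responder(gen)
  for (mode in c("mle", "proportions-ls")) {
    fit <- fit_psychometric(tab, 1, fit_mode = mode)
    expect_lt(abs(fit$pse - gen$mu), 15, label = mode)
    expect_lt(abs(fit$jnd - gen$jnd), 15, label = mode)
  }
})

test_that("numeric inversion of the fitted curve reproduces s * ln 3", {
  for (s in c(5, 10, 22.9, 80)) {
    tab <- simulate_responder(responder_params(mu = -10, jnd = s * log(3),
                                               seed = 2))
    fit <- fit_psychometric(tab, 1)
    expect_equal(jnd_from_curve(fit), fit$s * log(3),
                 tolerance = 1e-6)
  }
  # closed form at s = 10 ms
  tab <- simulate_responder(responder_params(seed = 3))
  fit <- fit_psychometric(tab, 1)
  fit$s <- 10
  expect_equal(jnd_from_curve(fit), 10 * log(3), tolerance = 1e-6)
  fit$s <- 20  # doubling s doubles the JND
  expect_equal(jnd_from_curve(fit), 20 * log(3), tolerance = 1e-6)
  fit$mu <- fit$mu + 300  # JND invariant to the curve's location
  expect_equal(jnd_from_curve(fit), 20 * log(3), tolerance = 1e-6)
  fit$converged <- FALSE
  expect_error(jnd_from_curve(fit), "converge")
})

test_that("group inference reproduces textbook one-sample t results", {
  # values {-1, 0, 1}: mean 0, t = 0, one-tailed p = 0.5 by symmetry
  g <- group_inference(c(-1, 0, 1), tail = "less")
  expect_equal(g$t_stat, 0)
  expect_equal(g$p_value, 0.5)
  expect_equal(g$df, 2)

  # t = 2.548, df = 2: one-tailed p from numeric integration of the
  # t density lands in [0.062, 0.064]
  p_brute <- t_upper_tail_brute(2.548, 2)
  expect_gt(p_brute, 0.062)
  expect_lt(p_brute, 0.064)
  summ <- t_test_from_summary(-18.37, 7.21, n = 3, tail = "less")
  expect_equal(summ$p_value, t_upper_tail_brute(18.37 / 7.21, 2),
               tolerance = 1e-6)

  # degenerate all-zero case is flagged with the p = 0.5 convention
  g0 <- group_inference(c(0, 0, 0), tail = "less")
  expect_true(g0$degenerate)
  expect_equal(g0$p_value, 0.5)
  expect_error(group_inference(c(3, 3, 3), tail = "less"), "unbounded")
  expect_error(group_inference(5, tail = "less"), "at least 2")
})

test_that("pooled curves average across participants with honest SEs", {
  one <- simulate_responder(responder_params(seed = 8), participant_id = "a")
  pc1 <- pooled_curve(one)
  # single participant: pooled equals the individual proportions, SE missing
  expect_equal(pc1$pooled$mean_proportion,
               response_proportions(one, "a")$proportion)
  expect_true(all(is.na(pc1$pooled$se_proportion)))

  # three identical participants: SE exactly 0 at every lag
  trip <- dplyr::bind_rows(
    dplyr::mutate(one, participant_id = "a"),
    dplyr::mutate(one, participant_id = "b"),
    dplyr::mutate(one, participant_id = "c"))
  pc3 <- pooled_curve(trip)
  expect_true(all(pc3$pooled$se_proportion == 0))
  expect_equal(pc3$pooled$n_participants, rep(3, 14))

  # a synthetic cohort's pooled proportions rise from ~0 to ~1 across lags
  coh <- simulate_cohort(cohort_spec(3, sd_mu = 0, sd_jnd = 0, seed = 4))
  pc <- pooled_curve(coh)
  expect_lt(pc$pooled$mean_proportion[pc$pooled$lag_ms == -120], 0.2)
  expect_gt(pc$pooled$mean_proportion[pc$pooled$lag_ms == 120], 0.8)
})

test_that("analyze_toj wires fits and group inference together", {
  coh <- simulate_cohort(cohort_spec(3, sd_mu = 0, sd_jnd = 0, seed = 21))
  res <- analyze_toj(coh, tail = "less")
  expect_equal(nrow(tidy(res)), 3)
  gl <- glance(res)
  expect_equal(gl$df, 2)
  expect_equal(gl$tail, "less")
  expect_equal(res$group$mean_pse, mean(tidy(res)$pse_ms))
  # tail is explicit and recorded; the two tails are complementary
  res_g <- analyze_toj(coh, tail = "greater")
  expect_equal(res_g$group$p_value + res$group$p_value, 1)
})

test_that("the pipeline recovers generating PSE and JND across many datasets", {
  sched <- schedule_trials(seed = 1)
  errs <- purrr::map_dfr(1:40, function(i) {
    tab <- simulate_responder(responder_params(seed = 300 + i), sched)
    fit <- fit_psychometric(tab, 1)
    tibble::tibble(pse_err = abs(fit$pse + 18.37),
                   jnd_err = abs(fit$jnd - 25.15))
  })
  expect_lte(median(errs$pse_err), 5)
  expect_lte(median(errs$jnd_err), 5)
})
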