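#' Synthetic responder and cohort specifications
#'
#' `responder_params()` parameterises a Bernoulli observer whose
#' probability of judging the vertical stimulus first follows the same
#' logistic the analysis fits: location `mu` (the PSE) and scale
#' `s = jnd / ln 3`, optionally mixed with a lapse rate. Defaults are the
#' published group values for this task (PSE -18.37 ms, JND 25.15 ms),
#' making parameter-recovery experiments well-posed. `cohort_spec()`
#' describes a group of such responders with normal between-participant
#' spread on `mu` and `jnd`.
#'
#' @param mu Cross-over point (PSE), ms.
#' @param jnd Just-noticeable difference, ms (> 0); implies
#'   `s = jnd / ln 3`.
#' @param lapse Stimulus-independent error probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return `responder_params()`: a list of class `responder_params`.
#' @export
responder_params <- function(mu = -18.37, jnd = 25.15, lapse = 0, seed = 1) {
  check_number(mu, "mu")
  check_number(jnd, "jnd", lower = .Machine$double.eps)
  check_number(lapse, "lapse", lower = 0, upper = 0.5 - 1e-12)
  structure(
    list(mu = mu, jnd = jnd, s = jnd / log(3), lapse = lapse, seed = seed),
    class = "responder_params"
  )
}

#' @rdname responder_params
#' @param n_participants Cohort size (default 3, the pilot group size).
#' @param sd_mu,sd_jnd Between-participant standard deviations, ms. The
#'   defaults (12.5 and 3.9 ms) are sqrt(3) times the published group
#'   standard errors, so a simulated 3-participant cohort shows a similar
#'   group SE — a calibration of the generator, not a published value.
#' @return `cohort_spec()`: a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 3, sd_mu = 12.5, sd_jnd = 3.9,
                        seed = 1) {
  check_number(n_participants, "n_participants", lower = 1)
  check_number(sd_mu, "sd_mu", lower = 0)
  check_number(sd_jnd, "sd_jnd", lower = 0)
  structure(
    list(n_participants = as.integer(n_participants), sd_mu = sd_mu,
         sd_jnd = sd_jnd, seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate one synthetic TOJ responder
#'
#' For each trial of the schedule the response is Bernoulli with
#' `P(vertical first) = lapse/2 + (1 - lapse) * logistic((lag - mu)/s)` —
#' the generative twin of the analysis model. Deterministic given the seed.
#'
#' @param params A [responder_params()].
#' @param schedule A [schedule_trials()] tibble.
#' @param participant_id Id recorded in the output rows.
#' @return A response tibble: `participant_id`, `trial_id`, `lag_ms`,
#'   `response`.
#' @examples
#' tab <- simulate_responder(responder_params(seed = 42))
#' mean(tab$response[tab$lag_ms > 0])
#' @export
simulate_responder <- function(params = responder_params(),
                               schedule = schedule_trials(),
                               participant_id = 1) {
  stopifnot(inherits(params, "responder_params"))
  p <- params$lapse / 2 +
    (1 - params$lapse) * logistic_p(schedule$lag_ms, params$mu, params$s)
  y <- with_seed(params$seed, rbinom(length(p), 1L, p))
  tibble(participant_id = participant_id,
         trial_id = schedule$trial_id,
         lag_ms = schedule$lag_ms,
         response = as.integer(y))
}

#' Simulate a cohort of synthetic responders
#'
#' Draws each participant's `(mu, jnd)` from normal distributions centred
#' on `responder_defaults` with the cohort's between-participant sds (jnd
#' truncated strictly positive), then simulates each with
#' [simulate_responder()] on the shared schedule.
#'
#' @param spec A [cohort_spec()].
#' @param responder_defaults Centre of the participant distribution, a
#'   [responder_params()].
#' @param schedule A [schedule_trials()] tibble shared by all participants.
#' @return A multi-participant response tibble (same columns as
#'   [simulate_responder()]); attribute `participants` holds the drawn
#'   per-participant parameters.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            responder_defaults = responder_params(),
                            schedule = schedule_trials()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  pars <- with_seed(spec$seed, {
    mu <- rnorm(n, responder_defaults$mu, spec$sd_mu)
    jnd <- rnorm(n, responder_defaults$jnd, spec$sd_jnd)
    jnd <- pmax(jnd, 1e-3)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    tibble(participant_id = seq_len(n), mu = mu, jnd = jnd, seed = seeds)
  })
  out <- purrr::pmap_dfr(pars, function(participant_id, mu, jnd, seed) {
    simulate_responder(
      responder_params(mu = mu, jnd = jnd,
                       lapse = responder_defaults$lapse, seed = seed),
      schedule, participant_id = participant_id)
  })
  attr(out, "participants") <- pars
  out
}

#' Simulate a full set of device recordings over a schedule
#'
#' One closed-loop [simulate_trial()] per schedule entry, each with an
#' independent noise stream derived from the base seed (seed + trial id),
#' emulating a complete 14 x 15 recording session.
#'
#' @param schedule A [schedule_trials()] tibble.
#' @param spec A [pulse_spec()] for the stimulus.
#' @param motor_v,motor_h,load,config Device configuration as in
#'   [simulate_trial()]; `config$seed` is the base seed.
#' @return A list of `trial_recording`s, one per schedule row, with a
#'   `manifest` attribute (tibble: `trial_id`, `lag_ms`, `seed`).
#' @export
simulate_recording_set <- function(schedule = schedule_trials(),
                                   spec = pulse_spec(),
                                   motor_v = motor_params(),
                                   motor_h = motor_params(),
                                   load = skin_load(),
                                   config = control_config()) {
  base_seed <- config$seed %||% 0
  recs <- purrr::map(seq_len(nrow(schedule)), function(i) {
    pair <- make_lagged_pair(spec, schedule$lag_ms[[i]])
    cfg <- config
    cfg$seed <- (base_seed + schedule$trial_id[[i]]) %% .Machine$integer.max
    simulate_trial(pair, motor_v, motor_h, load, cfg)
  })
  attr(recs, "manifest") <- tibble(
    trial_id = schedule$trial_id, lag_ms = schedule$lag_ms,
    seed = (base_seed + schedule$trial_id) %% .Machine$integer.max)
  recs
}
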