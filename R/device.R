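#' Motor, load and controller parameter objects
#'
#' `motor_params()` lumps the DC motor's electromagnetic behaviour into a
#' linear current-to-force map (`force_constant`, N per A — torque constant
#' divided by pulley radius), a first-order electrical time constant, and a
#' current limit. `skin_load()` is the quasi-static Kelvin-Voigt description
#' of the facial tissue the wire pulls against; `stiffness = damping = 0`
#' encodes the unloaded bench condition (no external device attached).
#' `control_config()` holds the PID gains of the current-error feedback
#' loop, the loop rate (100 Hz, i.e. 10 ms timing precision) and the
#' current-sensing noise level.
#'
#' @param force_constant N per A of motor current.
#' @param terminal_resistance Winding resistance, ohm.
#' @param electrical_time_constant First-order lag of the current loop, s.
#' @param max_current Hard limit on commanded/driven current, A.
#' @return `motor_params()`: a list of class `motor_params`.
#' @export
motor_params <- function(force_constant = 1, terminal_resistance = 2.1,
                         electrical_time_constant = 1e-3, max_current = 4) {
  check_number(force_constant, "force_constant", lower = .Machine$double.eps)
  check_number(terminal_resistance, "terminal_resistance",
               lower = .Machine$double.eps)
  check_number(electrical_time_constant, "electrical_time_constant",
               lower = .Machine$double.eps)
  check_number(max_current, "max_current", lower = .Machine$double.eps)
  structure(
    list(force_constant = force_constant,
         terminal_resistance = terminal_resistance,
         electrical_time_constant = electrical_time_constant,
         max_current = max_current),
    class = "motor_params"
  )
}

#' @rdname motor_params
#' @param stiffness Skin stiffness, N/m (>= 0).
#' @param damping Skin damping, N s/m (>= 0).
#' @param moving_mass Mass of tab + wire take-up, kg (> 0); carried for
#'   completeness, it does not enter the quasi-static force balance.
#' @return `skin_load()`: a list of class `skin_load`.
#' @export
skin_load <- function(stiffness = 0, damping = 0, moving_mass = 5e-3) {
  check_number(stiffness, "stiffness", lower = 0)
  check_number(damping, "damping", lower = 0)
  check_number(moving_mass, "moving_mass", lower = .Machine$double.eps)
  structure(
    list(stiffness = stiffness, damping = damping, moving_mass = moving_mass),
    class = "skin_load"
  )
}

#' @rdname motor_params
#' @param kp,ki,kd PID gains on the current error (drive per A, per A s,
#'   per A/s). Defaults were tuned once in unloaded simulation to track the
#'   2 N pulse peak within 5 percent.
#' @param sample_rate Control-loop rate, Hz.
#' @param noise_sd Gaussian current-sensing noise sd, A. The default is
#'   calibrated so per-trial onset-lag jitter has sd of about 1.5 ms.
#' @param seed Integer seed for the sensing noise.
#' @param feedforward If `TRUE` (as in the block diagram) the target current
#'   is injected ahead of the PID correction; `FALSE` leaves tracking to the
#'   feedback path alone.
#' @return `control_config()`: a list of class `control_config`.
#' @export
control_config <- function(kp = 0.4, ki = 2, kd = 0.005, sample_rate = 100,
                           noise_sd = 0.03, seed = 1, feedforward = TRUE) {
  check_number(kp, "kp", lower = 0)
  check_number(ki, "ki", lower = 0)
  check_number(kd, "kd", lower = 0)
  check_number(sample_rate, "sample_rate", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(kp = kp, ki = ki, kd = kd, sample_rate = sample_rate,
         noise_sd = noise_sd, seed = seed,
         feedforward = isTRUE(feedforward)),
    class = "control_config"
  )
}

#' Inverse motor model: target force to target current
#'
#' The feedforward leg of the force controller: divides the requested force
#' by the motor's force constant and clips to `[0, max_current]`. Negative
#' forces are rejected — the wire-and-tab coupling can only pull the skin.
#'
#' @param target_force Requested force, N (vectorised); must be >= 0.
#' @param params A [motor_params()].
#' @return Target current in A, same length as `target_force`.
#' @examples
#' inverse_motor_model(2, motor_params(force_constant = 1))
#' @export
inverse_motor_model <- function(target_force, params = motor_params()) {
  if (!is.numeric(target_force) || !all(is.finite(target_force))) {
    abort("`target_force` must be finite numeric.")
  }
  if (any(target_force < 0)) {
    abort("negative target force requested: the skin coupling can only pull, not push.")
  }
  pmin(target_force / params$force_constant, params$max_current)
}

#' Forward motor model: current to force
#'
#' The linear electromagnetic map `force = force_constant * current`, the
#' exact inverse of [inverse_motor_model()] inside the clip region. Used to
#' express recorded motor currents in force units for analysis.
#'
#' @inheritParams inverse_motor_model
#' @param current Motor current, A (vectorised).
#' @return Force in N.
#' @export
forward_force <- function(current, params = motor_params()) {
  if (!is.numeric(current) || !all(is.finite(current))) {
    abort("`current` must be finite numeric.")
  }
  params$force_constant * current
}

#' One step of the discrete PID controller
#'
#' Backward-Euler integral, first-difference derivative on the error, no
#' derivative filtering. The state carries the accumulated integral and the
#' previous error; `dt` is fixed at `1/sample_rate` for the life of the
#' state. The integral term is clamped to `integral_limit` (anti-windup).
#'
#' @param error Current error, A.
#' @param state Controller state from [pid_state()] or a previous call.
#' @param config A [control_config()].
#' @param integral_limit Clamp on `ki * integral` in drive units.
#' @return A list with `drive` and the updated `state`.
#' @export
pid_step <- function(error, state = pid_state(), config = control_config(),
                     integral_limit = Inf) {
  if (!is.numeric(error) || length(error) != 1L || !is.finite(error)) {
    abort("`error` must be a single finite number.")
  }
  dt <- 1 / config$sample_rate
  integral <- state$integral + error * dt
  if (config$ki > 0 && is.finite(integral_limit)) {
    integral <- max(min(integral, integral_limit / config$ki),
                    -integral_limit / config$ki)
  }
  deriv <- if (state$fresh) 0 else (error - state$prev_error) / dt
  drive <- config$kp * error + config$ki * integral + config$kd * deriv
  list(drive = drive,
       state = list(integral = integral, prev_error = error, fresh = FALSE))
}

#' @rdname pid_step
#' @export
pid_state <- function() list(integral = 0, prev_error = 0, fresh = TRUE)

# Quasi-static load divider: fraction of the electrically available force
# actually delivered against a Kelvin-Voigt skin, relative to the drive's
# reference stiffness/damping. 1 when unloaded; strictly decreasing in both
# stiffness and damping.
load_attenuation <- function(load, k_ref = 2000, c_ref = 50) {
  1 / (1 + load$stiffness / k_ref + load$damping / c_ref)
}

simulate_channel <- function(target, motor, load, config, noise) {
  n <- nrow(target)
  dt <- 1 / config$sample_rate
  phi <- exp(-dt / motor$electrical_time_constant)
  alpha <- load_attenuation(load)
  i_target <- inverse_motor_model(target$force, motor)
  i_elec <- 0
  i_meas_prev <- 0
  st <- pid_state()
  out <- numeric(n)
  for (k in seq_len(n)) {
    e <- i_target[[k]] - i_meas_prev
    step <- pid_step(e, st, config, integral_limit = motor$max_current)
    st <- step$state
    u <- step$drive + if (config$feedforward) i_target[[k]] else 0
    u <- min(max(u, 0), motor$max_current)
    i_elec <- u + (i_elec - u) * phi
    i_load <- alpha * i_elec
    i_meas <- i_load + noise[[k]]
    i_meas_prev <- i_meas
    out[[k]] <- i_meas
  }
  force_trace(forward_force(out, motor), sample_rate = config$sample_rate,
              t0 = target$time[[1]])
}

#' Simulate one closed-loop trial of the two-motor device
#'
#' Steps, per channel, the force-control loop of the device: the target
#' force is converted to a target current by the inverse motor model; the
#' error between target and measured current drives a PID controller (plus
#' optional feedforward of the target current); the drive passes through a
#' first-order electrical lag and a quasi-static spring-damper load divider;
#' Gaussian sensing noise is added to the measured current, which closes the
#' loop and is recorded. Measured currents are returned in force units via
#' the linear current-force relationship, mirroring how the physical device
#' logs target input and motor current for later analysis.
#'
#' @param pulse_pair A list with `vertical` and `horizontal` target
#'   [force_trace()]s on a common grid (see [make_lagged_pair()]) and
#'   optionally `lag_ms`.
#' @param motor_v,motor_h [motor_params()] per channel.
#' @param load A [skin_load()], shared by both channels.
#' @param config A [control_config()]; its `sample_rate` must match the
#'   target traces and its `seed` makes the run reproducible.
#' @return A list of class `trial_recording` with elements `commanded_lag`
#'   (ms), `target_v`, `target_h`, `measured_v`, `measured_h`.
#' @examples
#' rec <- simulate_trial(make_lagged_pair(lag_ms = 40),
#'                       config = control_config(noise_sd = 0))
#' @export
simulate_trial <- function(pulse_pair, motor_v = motor_params(),
                           motor_h = motor_params(), load = skin_load(),
                           config = control_config()) {
  tv <- pulse_pair$vertical
  th <- pulse_pair$horizontal
  stopifnot_same_grid(tv, th, "target traces")
  if (abs(trace_sample_rate(tv) - config$sample_rate) > 1e-9) {
    abort(sprintf(
      "target traces sampled at %g Hz but the control loop runs at %g Hz.",
      trace_sample_rate(tv), config$sample_rate))
  }
  n <- nrow(tv)
  noise <- with_seed(config$seed, {
    if (config$noise_sd > 0) {
      list(v = rnorm(n, 0, config$noise_sd), h = rnorm(n, 0, config$noise_sd))
    } else {
      list(v = numeric(n), h = numeric(n))
    }
  })
  structure(
    list(commanded_lag = pulse_pair$lag_ms %||% NA_real_,
         target_v = tv, target_h = th,
         measured_v = simulate_channel(tv, motor_v, load, config, noise$v),
         measured_h = simulate_channel(th, motor_h, load, config, noise$h)),
    class = "trial_recording"
  )
}

#' Spatial trajectory of the combined two-motor stimulus
#'
#' Pairs the horizontal and vertical force samples pointwise, giving the
#' trajectory the stimulus traces in the horizontal-vertical force plane.
#' For lag near 0 the target trajectory lies on the diagonal (the two
#' motors pull together); near a half-cycle lag (about 83 ms for the 6 Hz
#' pulse) one channel is near zero while the other peaks, tracing an
#' L-shaped loop close to a right triangle.
#'
#' @param rec A `trial_recording` from [simulate_trial()].
#' @param which `"target"` or `"measured"`.
#' @return A tibble with columns `time`, `horizontal`, `vertical` (N).
#' @export
spatial_trajectory <- function(rec, which = c("target", "measured")) {
  stopifnot(inherits(rec, "trial_recording"))
  which <- match.arg(which)
  v <- if (which == "target") rec$target_v else rec$measured_v
  h <- if (which == "target") rec$target_h else rec$measured_h
  tibble(time = v$time, horizontal = h$force, vertical = v$force)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording: lag %s ms, %d samples @ %g Hz, peak target %.3g N, peak measured %.3g N>\n",
    format(x$commanded_lag), nrow(x$target_v),
    trace_sample_rate(x$target_v),
    max(x$target_v$force, x$target_h$force),
    max(x$measured_v$force, x$measured_h$force)))
  invisible(x)
}
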