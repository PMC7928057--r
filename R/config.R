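#' Default run configuration
#'
#' The nested configuration driving the full pipeline, with every default
#' matching the device's printed operating point where one exists: 6 Hz /
#' 2 N pulse, 14 signed lags, 15 repetitions, 100 Hz control loop, 1000 Hz
#' analysis rate, 10 percent onset threshold.
#'
#' @param seed Base seed recorded in the config.
#' @return A nested list of class `run_config` with sections `stimulus`,
#'   `design`, `device` (`motor_v`, `motor_h`, `load`, `control`) and
#'   `analysis`.
#' @export
default_config <- function(seed = 1) {
  structure(
    list(
      stimulus = list(frequency = 6, peak = 2, sample_rate = 100,
                      pre_silence = 0.2, post_silence = 0.3),
      design = list(lags = design_lags(), reps = 15, seed = seed),
      device = list(
        motor_v = unclass(motor_params()),
        motor_h = unclass(motor_params()),
        load = unclass(skin_load()),
        control = unclass(control_config(seed = seed))
      ),
      analysis = list(target_rate = 1000, smooth_window = 11,
                      threshold_frac = 0.10, fit_mode = "mle",
                      tail = "less"),
      toj = list(mu = -18.37, jnd = 25.15, lapse = 0, n_participants = 3,
                 sd_mu = 12.5, sd_jnd = 3.9, seed = seed)
    ),
    class = "run_config"
  )
}

merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) {
      abort(sprintf("unknown configuration key: `%s`.", full))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(sprintf("`%s` must be a section (got a scalar).", full))
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], c(path, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  # constructors re-run all range checks; failures name the offending field
  do.call(pulse_spec, cfg$stimulus)
  do.call(motor_params, cfg$device$motor_v)
  do.call(motor_params, cfg$device$motor_h)
  do.call(skin_load, cfg$device$load)
  do.call(control_config, cfg$device$control)
  check_number(cfg$design$reps, "design.reps", lower = 1)
  if (length(cfg$design$lags) < 1) abort("design.lags must be non-empty.")
  check_number(cfg$analysis$threshold_frac, "analysis.threshold_frac",
               lower = .Machine$double.eps, upper = 1)
  check_number(cfg$analysis$target_rate, "analysis.target_rate",
               lower = cfg$stimulus$sample_rate)
  if (!cfg$analysis$fit_mode %in% c("mle", "proportions-ls")) {
    abort("analysis.fit_mode must be 'mle' or 'proportions-ls'.")
  }
  if (!cfg$analysis$tail %in% c("less", "greater", "two-sided")) {
    abort("analysis.tail must be 'less', 'greater' or 'two-sided'.")
  }
  do.call(responder_params,
          cfg$toj[c("mu", "jnd", "lapse")])
  invisible(cfg)
}

#' Load, validate and save run configurations
#'
#' `load_config()` reads a JSON configuration file, overlays it on
#' [default_config()] (unknown keys are an error naming the offending
#' field), and validates every value; an empty file yields all defaults.
#' `save_config()` writes a config as canonical JSON; a save/load
#' round-trip is the identity. `config_hash()` is the MD5 of the canonical
#' JSON, used to stamp outputs.
#'
#' @param path File path.
#' @return `load_config()`: a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nzchar(trimws(txt))) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    list()
  }
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname load_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}
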