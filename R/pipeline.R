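#' Read and write device trace files
#'
#' Traces are exchanged as long-format CSV (UTF-8, comma separated, header
#' row): `trial_id`, `channel` (`vertical`/`horizontal`), `kind`
#' (`target`/`measured`), `time_s`, `force_N`.
#'
#' @param recordings A list of `trial_recording`s.
#' @param path Output CSV path.
#' @return `write_traces_csv()` returns `path` invisibly;
#'   `read_traces_csv()` returns a list of `trial_recording`s keyed by
#'   trial, with `commanded_lag` taken from `schedule` when supplied.
#' @export
write_traces_csv <- function(recordings, path) {
  rows <- purrr::map_dfr(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    one <- function(tr, channel, kind) {
      tibble(trial_id = i, channel = channel, kind = kind,
             time_s = tr$time, force_N = tr$force)
    }
    dplyr::bind_rows(one(rec$target_v, "vertical", "target"),
                     one(rec$target_h, "horizontal", "target"),
                     one(rec$measured_v, "vertical", "measured"),
                     one(rec$measured_h, "horizontal", "measured"))
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param schedule Optional [schedule_trials()] tibble supplying the
#'   commanded lag per trial.
#' @export
read_traces_csv <- function(path, schedule = NULL) {
  rows <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "channel", "kind", "time_s", "force_N")
  if (!all(need %in% names(rows))) {
    abort(paste0("trace CSV needs columns: ", paste(need, collapse = ", ")))
  }
  ids <- sort(unique(rows$trial_id))
  purrr::map(ids, function(id) {
    sub <- dplyr::filter(rows, .data$trial_id == id)
    pick <- function(channel, kind) {
      d <- dplyr::filter(sub, .data$channel == !!channel,
                         .data$kind == !!kind)
      as_force_trace(tibble(time = d$time_s, force = d$force_N))
    }
    lag <- if (!is.null(schedule)) {
      schedule$lag_ms[match(id, schedule$trial_id)]
    } else {
      NA_real_
    }
    structure(
      list(commanded_lag = lag,
           target_v = pick("vertical", "target"),
           target_h = pick("horizontal", "target"),
           measured_v = pick("vertical", "measured"),
           measured_h = pick("horizontal", "measured")),
      class = "trial_recording")
  })
}

#' Read and write TOJ response tables
#'
#' Response CSV dialect: `participant_id`, `trial_id`, `lag_ms`,
#' `response` (0/1), comma separated with a header row.
#'
#' @param table A response tibble.
#' @param path CSV path.
#' @export
write_responses_csv <- function(table, path) {
  check_response_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_response_table(tab)
  tab
}

#' Run the complete simulation-and-analysis pipeline
#'
#' Executes both evaluation arms on purely synthetic inputs: (1) device
#' arm — build the lagged-pulse schedule, simulate every closed-loop trial,
#' and verify delivered lags (upsample, 10-percent onsets, condition means,
#' Pearson correlation); (2) perceptual arm — simulate a responder cohort
#' on the same schedule and run the psychometric analysis (per-participant
#' PSE/JND, group t-test). When `out_dir` is given, traces, responses,
#' summaries and a provenance-stamped report (package version, config
#' hash, seed) are written there.
#'
#' @param config A `run_config` (see [default_config()] / [load_config()]).
#' @param out_dir Optional output directory, created if needed.
#' @return A list of class `pipeline_report`: `schedule`, `lag_analysis`,
#'   `toj`, `config`, `provenance`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  spec <- do.call(pulse_spec, config$stimulus)
  schedule <- schedule_trials(config$design$lags, config$design$reps,
                              config$design$seed)

  recs <- simulate_recording_set(
    schedule, spec,
    motor_v = do.call(motor_params, config$device$motor_v),
    motor_h = do.call(motor_params, config$device$motor_h),
    load = do.call(skin_load, config$device$load),
    config = do.call(control_config, config$device$control))
  lags <- analyze_lags(recs,
                       target_rate = config$analysis$target_rate,
                       smooth_window = config$analysis$smooth_window,
                       threshold_frac = config$analysis$threshold_frac)

  responses <- simulate_cohort(
    cohort_spec(config$toj$n_participants, config$toj$sd_mu,
                config$toj$sd_jnd, config$toj$seed),
    responder_params(config$toj$mu, config$toj$jnd, config$toj$lapse),
    schedule)
  toj <- analyze_toj(responses, tail = config$analysis$tail,
                     fit_mode = config$analysis$fit_mode)

  provenance <- list(
    package_version = as.character(utils::packageVersion("skinstretch")),
    config_hash = config_hash(config),
    seed = config$design$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))

  report <- structure(
    list(schedule = schedule, lag_analysis = lags, toj = toj,
         responses = responses, config = config, provenance = provenance),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_config(config, file.path(out_dir, "config.json"))
    readr::write_csv(
      tibble(trial_id = schedule$trial_id, lag_ms = schedule$lag_ms,
             seed = config$design$seed),
      file.path(out_dir, "schedule.csv"))
    write_traces_csv(recs, file.path(out_dir, "traces.csv"))
    readr::write_csv(lags$trial_lags, file.path(out_dir, "trial_lags.csv"))
    readr::write_csv(lags$condition_summary,
                     file.path(out_dir, "condition_summary.csv"))
    write_responses_csv(responses, file.path(out_dir, "responses.csv"))
    readr::write_csv(tidy(toj), file.path(out_dir, "participant_fits.csv"))
    jsonlite::write_json(
      c(provenance,
        list(lag_correlation = glance(lags$correlation),
             group = if (!is.null(toj$group)) glance(toj$group))),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  schedule: %d trials, %d lag conditions\n",
              nrow(x$schedule), length(unique(x$schedule$lag_ms))))
  print(x$lag_analysis$correlation)
  print(x$toj)
  cat(sprintf("  provenance: skinstretch %s, config %s, seed %s\n",
              x$provenance$package_version,
              substr(x$provenance$config_hash, 1, 8),
              format(x$provenance$seed)))
  invisible(x)
}
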