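#' Battery configuration
#'
#' Builds and validates the configuration of the five-task battery. The
#' defaults reproduce the deployed battery: 35 simple visual reaction time
#' (sVRT) trials with a uniform 4--8 s warning interval, 70 Go/No-Go trials
#' (half targets), 8 visual-recognition sequences whose display durations grow
#' from 2.5 s to 10 s, a 20-trial Simon task (half congruent), and a 30-stimulus
#' three-block interference task.
#'
#' @param svrt_n_trials Number of sVRT trials (default 35).
#' @param svrt_interval_range_s Length-2 numeric, uniform range (seconds) of
#'   the random interval before the go signal (default `c(4, 8)`).
#' @param gonogo_n_trials Number of Go/No-Go trials (default 70).
#' @param gonogo_target_fraction Fraction of target (square) trials, strictly
#'   inside (0, 1) so both response and inhibition trials exist (default 0.5).
#' @param vr_n_sequences Number of visual-recognition sequences (default 8).
#' @param vr_duration_range_s Length-2 numeric, display durations (seconds) of
#'   the first and last sequence; intermediate sequences are interpolated
#'   linearly (default `c(2.5, 10)`).
#' @param simon_n_trials Number of Simon trials (default 20).
#' @param simon_congruent_fraction Fraction of congruent Simon trials,
#'   strictly inside (0, 1) (default 0.5).
#' @param interference_total_stimuli Total stimuli across the three
#'   interference blocks; must be divisible by 3 (default 30).
#' @param response_window_s Response window (seconds) after stimulus onset; a
#'   trial with no valid tap inside the window is an omission (default 2).
#' @param vr_version Alternate form of the visual-recognition task, `"A"` or
#'   `"B"`; the two forms share structure but use disjoint image identifiers.
#'
#' @return A validated list of class `battery_config`.
#' @examples
#' cfg <- battery_config()
#' cfg$svrt_n_trials
#' @export
battery_config <- function(svrt_n_trials = 35,
                           svrt_interval_range_s = c(4, 8),
                           gonogo_n_trials = 70,
                           gonogo_target_fraction = 0.5,
                           vr_n_sequences = 8,
                           vr_duration_range_s = c(2.5, 10),
                           simon_n_trials = 20,
                           simon_congruent_fraction = 0.5,
                           interference_total_stimuli = 30,
                           response_window_s = 2,
                           vr_version = c("A", "B")) {
  vr_version <- match.arg(vr_version)
  config <- structure(
    list(
      svrt_n_trials = as.integer(svrt_n_trials),
      svrt_interval_range_s = as.numeric(svrt_interval_range_s),
      gonogo_n_trials = as.integer(gonogo_n_trials),
      gonogo_target_fraction = as.numeric(gonogo_target_fraction),
      vr_n_sequences = as.integer(vr_n_sequences),
      vr_duration_range_s = as.numeric(vr_duration_range_s),
      simon_n_trials = as.integer(simon_n_trials),
      simon_congruent_fraction = as.numeric(simon_congruent_fraction),
      interference_total_stimuli = as.integer(interference_total_stimuli),
      response_window_s = as.numeric(response_window_s),
      vr_version = vr_version
    ),
    class = "battery_config"
  )
  validate_battery_config(config)
}

#' Validate a battery configuration
#'
#' Checks every field of a [battery_config()] and signals a configuration
#' error naming the offending field on the first violation.
#'
#' @param config A `battery_config` (or a bare list with the same fields).
#' @return The validated configuration, invisibly usable in a pipe.
#' @export
validate_battery_config <- function(config) {
  chk_count <- function(field) {
    v <- config[[field]]
    if (length(v) != 1 || is.na(v) || v < 1) {
      abort_config(field, "must be a positive count")
    }
  }
  chk_fraction <- function(field) {
    v <- config[[field]]
    if (length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      abort_config(field, "must lie strictly between 0 and 1")
    }
  }
  chk_range <- function(field) {
    v <- config[[field]]
    if (length(v) != 2 || any(is.na(v)) || any(v <= 0) || v[1] >= v[2]) {
      abort_config(field, "must be an increasing pair of positive seconds")
    }
  }
  chk_count("svrt_n_trials")
  chk_count("gonogo_n_trials")
  chk_count("vr_n_sequences")
  chk_count("simon_n_trials")
  chk_count("interference_total_stimuli")
  chk_fraction("gonogo_target_fraction")
  chk_fraction("simon_congruent_fraction")
  chk_range("svrt_interval_range_s")
  chk_range("vr_duration_range_s")
  if (config$interference_total_stimuli %% 3L != 0L) {
    abort_config("interference_total_stimuli", "must be divisible by 3 (three blocks)")
  }
  if (length(config$response_window_s) != 1 || is.na(config$response_window_s) ||
      config$response_window_s <= 0) {
    abort_config("response_window_s", "must be a positive number of seconds")
  }
  if (!config$vr_version %in% c("A", "B")) {
    abort_config("vr_version", "must be \"A\" or \"B\"")
  }
  config
}

#' Task kinds of the battery
#'
#' The five tasks in battery order: simple visual reaction time, Go/No-Go,
#' visual recognition, Simon, interference.
#'
#' @return Character vector of the five task identifiers.
#' @export
task_kinds <- function() {
  c("svrt", "gonogo", "visual_recognition", "simon", "interference")
}

#' Planned duration of a task at the interval midpoint
#'
#' For the interval-paced tasks (sVRT and Go/No-Go) the planned duration is
#' the trial count times the midpoint of the inter-stimulus interval range;
#' e.g. 70 Go/No-Go trials at the 6 s midpoint of 4--8 s give 7 minutes.
#'
#' @param config A [battery_config()].
#' @param task `"svrt"` or `"gonogo"`.
#' @return Planned duration in minutes.
#' @examples
#' planned_task_duration_min(battery_config(), "gonogo") # 7
#' @export
planned_task_duration_min <- function(config, task = c("svrt", "gonogo")) {
  task <- match.arg(task)
  validate_battery_config(config)
  if (task == "svrt") {
    config$svrt_n_trials * mean(config$svrt_interval_range_s) / 60
  } else {
    config$gonogo_n_trials * mean(config$svrt_interval_range_s) / 60
  }
}

#' @export
print.battery_config <- function(x, ...) {
  cat("<battery_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = "-")))
  }
  invisible(x)
}
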