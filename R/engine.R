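# Event-driven session engine.
#
# The engine replays a tap stream against a schedule's absolute timeline and
# enforces the touch-input contract: response keys are inactive until
# stimulus onset, taps before onset are ignored (but counted), only the first
# valid in-window tap of a trial is a response, and surplus taps are
# suppressed without ever carrying into later trials. The response window is
# half-open — a tap exactly at the window close is too late and the trial is
# an omission.

# Keys the engine treats as active responses per task; anything else tapped
# during a trial is logged and suppressed, mirroring stray touch noise.
valid_keys_for <- function(task) {
  switch(task,
    svrt = "stimulus_area",
    gonogo = "stimulus_area",
    visual_recognition = c("yes", "no"),
    simon = c("left", "right"),
    interference = c("left", "right"),
    character(0)
  )
}

ALL_KEYS <- c("left", "right", "yes", "no", "stimulus_area")

#' Classify a trial response
#'
#' Maps a (trial, response) pair to one of the five outcome classes. Go/No-Go
#' non-targets yield `correct_rejection` when withheld and `false_alarm` when
#' tapped; trials requiring a response yield `omission` when withheld, `hit`
#' on the correct key, and otherwise `wrong_key` — except a "yes" on an
#' unseen recognition probe, which is a `false_alarm`.
#'
#' @param task Task identifier (see [task_kinds()]).
#' @param is_target Logical, whether the stimulus demands the "go"/"yes"
#'   response.
#' @param requires_response Logical, whether any response is expected.
#' @param correct_key Correct key for the trial (`NA` for withhold trials).
#' @param responded Logical, whether a valid in-window tap occurred.
#' @param response_key Key of the response (`NA` if none).
#' @return Character vector of classifications (vectorised over arguments).
#' @examples
#' classify_response("gonogo", FALSE, FALSE, NA, TRUE, "stimulus_area")
#' @export
classify_response <- function(task, is_target, requires_response, correct_key,
                              responded, response_key) {
  dplyr::case_when(
    !responded & requires_response ~ "omission",
    !responded ~ "correct_rejection",
    responded & !requires_response ~ "false_alarm",
    response_key == correct_key ~ "hit",
    task == "visual_recognition" & response_key == "yes" ~ "false_alarm",
    TRUE ~ "wrong_key"
  )
}

validate_tap_stream <- function(taps) {
  if (!all(c("timestamp_ms", "key") %in% names(taps))) {
    abort_input("tap stream must have columns `timestamp_ms` and `key`")
  }
  if (nrow(taps) == 0) return(taps)
  if (is.unsorted(taps$timestamp_ms)) {
    abort_input("tap stream timestamps must be non-decreasing")
  }
  bad <- !taps$key %in% ALL_KEYS
  if (any(bad)) {
    abort_input(sprintf("unknown tap key(s): %s",
                        paste(unique(taps$key[bad]), collapse = ", ")))
  }
  taps
}

#' Run a session: replay a tap stream through the engine
#'
#' Consumes a schedule and an ordered tap stream and produces one outcome per
#' scheduled trial plus a replayable event log. Each tap belongs to the trial
#' whose `[open, close)` interval contains it; taps before that trial's
#' stimulus onset, taps on inactive keys, and any tap after the trial's first
#' valid response are counted in `n_suppressed_taps` and never become
#' responses — in particular a double tap can never answer the next stimulus.
#'
#' @param schedule A `battery_schedule` from [generate_battery()] or
#'   [as_battery_schedule()].
#' @param taps Tibble of taps with `timestamp_ms` (integer ms from session
#'   start, non-decreasing) and `key`.
#' @param session_id Optional identifier stored in the log.
#' @return An `event_log`: list with `session_id`, `seed`, `schedule`, the
#'   full `events` tibble (trial/stimulus markers interleaved with taps) and
#'   the `outcomes` tibble (`task`, `trial_index`, `responded`,
#'   `response_key`, `rt_ms`, `classification`, `n_suppressed_taps`, ...).
#' @examples
#' cfg <- battery_config(svrt_n_trials = 2)
#' sched <- as_battery_schedule(generate_svrt_schedule(cfg, 1), cfg, 1)
#' taps <- tibble::tibble(
#'   timestamp_ms = sched$trials$onset_ms[1] + 300L, key = "stimulus_area"
#' )
#' run_session(sched, taps)$outcomes
#' @export
run_session <- function(schedule, taps, session_id = "session") {
  stopifnot(inherits(schedule, "battery_schedule"))
  trials <- schedule$trials
  taps <- validate_tap_stream(taps)

  n_trial <- nrow(trials)
  ts <- as.integer(taps$timestamp_ms)
  key <- as.character(taps$key)

  # assign each tap to the trial whose [open, close) interval holds it;
  # windows tile the session, so findInterval on the open times suffices
  tap_trial <- findInterval(ts, trials$trial_open_ms)
  tap_trial[ts < 0 | ts >= trials$close_ms[n_trial]] <- NA_integer_

  in_window <- !is.na(tap_trial) &
    ts >= trials$onset_ms[pmax(tap_trial, 1L)] &
    ts < trials$close_ms[pmax(tap_trial, 1L)]
  key_active <- purrr::map2_lgl(
    key, tap_trial,
    ~ !is.na(.y) && .x %in% valid_keys_for(trials$task[.y])
  )
  candidate <- in_window & key_active
  is_response <- candidate & !duplicated(ifelse(candidate, tap_trial, NA_integer_),
                                         incomparables = NA)

  resp_idx <- which(is_response)
  responded <- logical(n_trial)
  response_key <- rep(NA_character_, n_trial)
  rt_ms <- rep(NA_integer_, n_trial)
  responded[tap_trial[resp_idx]] <- TRUE
  response_key[tap_trial[resp_idx]] <- key[resp_idx]
  rt_ms[tap_trial[resp_idx]] <- ts[resp_idx] - trials$onset_ms[tap_trial[resp_idx]]

  n_suppressed <- tabulate(tap_trial[!is_response & !is.na(tap_trial)], n_trial)

  outcomes <- tibble::tibble(
    task = trials$task,
    trial_index = trials$trial_index,
    block_index = trials$block_index,
    sequence_index = trials$sequence_index,
    is_target = trials$is_target,
    congruent = trials$congruent,
    responded = responded,
    response_key = response_key,
    rt_ms = rt_ms,
    classification = classify_response(
      trials$task, trials$is_target, trials$requires_response,
      trials$correct_key, responded, response_key
    ),
    n_suppressed_taps = n_suppressed
  )

  markers <- tibble::tibble(
    timestamp_ms = c(trials$trial_open_ms, trials$onset_ms, trials$close_ms),
    kind = rep(c("trial_open", "stimulus_onset", "trial_close"), each = n_trial),
    key = NA_character_,
    trial_index = rep(trials$trial_index, 3L),
    task = rep(trials$task, 3L)
  )
  tap_events <- tibble::tibble(
    timestamp_ms = as.integer(ts),
    kind = rep("tap", length(ts)),
    key = as.character(key),
    trial_index = as.integer(ifelse(is.na(tap_trial), NA,
                                    trials$trial_index[pmax(tap_trial, 1L)])),
    task = as.character(ifelse(is.na(tap_trial), NA,
                               trials$task[pmax(tap_trial, 1L)]))
  )
  events <- dplyr::arrange(dplyr::bind_rows(markers, tap_events),
                           .data$timestamp_ms, .data$kind)

  structure(
    list(session_id = session_id, seed = schedule$seed, schedule = schedule,
         events = events, outcomes = outcomes),
    class = "event_log"
  )
}

#' Replay an event log
#'
#' Extracts the tap stream from a log and runs it through the engine again;
#' by the engine's determinism the outcomes must reproduce the stored ones
#' exactly. Used as the integrity/regression check for recorded sessions.
#'
#' @param log An `event_log` from [run_session()].
#' @return A fresh `event_log` whose outcomes equal the input's.
#' @export
replay <- function(log) {
  stopifnot(inherits(log, "event_log"))
  taps <- dplyr::filter(log$events, .data$kind == "tap")
  out <- run_session(log$schedule, taps[, c("timestamp_ms", "key")],
                     session_id = log$session_id)
  if (!identical(out$outcomes, log$outcomes)) {
    abort_input("corrupted log: replayed outcomes differ from stored outcomes",
                class = "tapbattery_integrity_error")
  }
  out
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %s: %d trials, %d taps\n", x$session_id,
              nrow(x$outcomes), sum(x$events$kind == "tap")))
  print(dplyr::count(x$outcomes, .data$task, .data$classification))
  invisible(x)
}
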