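# File formats: schedules as JSON, event logs as JSON-lines, cohorts and
# reports as CSV. Every reader validates on load; every writer produces a
# stable field order so identical objects serialize byte-identically.

schedule_json <- function(schedule) {
  jsonlite::toJSON(
    list(
      seed = schedule$seed,
      config = unclass(schedule$config),
      trials = schedule$trials,
      vr_sequences = schedule$vr_sequences
    ),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null",
    na = "null", pretty = FALSE
  )
}

#' Write a battery schedule to JSON
#'
#' @param schedule A `battery_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "battery_schedule"))
  writeLines(schedule_json(schedule), path, useBytes = TRUE)
  invisible(path)
}

#' Read a battery schedule from JSON
#'
#' @param path Path written by [write_schedule()].
#' @return A `battery_schedule`.
#' @export
read_schedule <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  config <- validate_battery_config(structure(raw$config, class = "battery_config"))
  trials <- tibble::as_tibble(raw$trials)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$block_index <- as.integer(trials$block_index)
  trials$sequence_index <- as.integer(trials$sequence_index)
  for (col in c("trial_open_ms", "onset_ms", "close_ms")) {
    trials[[col]] <- as.integer(trials[[col]])
  }
  if (!"probe_id" %in% names(trials)) trials$probe_id <- NA_character_
  trials$probe_id <- as.character(trials$probe_id)
  vr <- raw$vr_sequences
  if (!is.null(vr)) {
    vr <- tibble::as_tibble(vr)
    vr$sequence_index <- as.integer(vr$sequence_index)
    vr$n_encoding <- as.integer(vr$n_encoding)
    vr$n_probes <- as.integer(vr$n_probes)
  }
  structure(
    list(seed = as.integer(raw$seed), config = config, trials = trials,
         vr_sequences = vr),
    class = "battery_schedule"
  )
}

#' Write an event log to JSON-lines
#'
#' One record per line: a header (session id, seed), then every event, then
#' every trial outcome, each tagged with a `record` field.
#'
#' @param log An `event_log`.
#' @param path Output file path.
#' @param with_schedule Embed the schedule in the header (default `TRUE`) so
#'   the log is self-contained and replayable.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, with_schedule = TRUE) {
  stopifnot(inherits(log, "event_log"))
  header <- list(record = "header", session_id = log$session_id,
                 seed = log$seed)
  if (with_schedule) {
    header$schedule <- jsonlite::fromJSON(schedule_json(log$schedule),
                                          simplifyDataFrame = FALSE)
  }
  line_of <- function(x) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  }
  events <- log$events
  events$record <- "event"
  outcomes <- log$outcomes
  outcomes$record <- "outcome"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    line_of(header),
    vapply(seq_len(nrow(events)),
           function(i) line_of(as.list(events[i, ])), character(1)),
    vapply(seq_len(nrow(outcomes)),
           function(i) line_of(as.list(outcomes[i, ])), character(1))
  ), con, useBytes = TRUE)
  invisible(path)
}

#' Read an event log from JSON-lines
#'
#' Validates the stream on load: the header must come first, event
#' timestamps must be non-decreasing, and outcome rows must be well-formed.
#'
#' @param path Path written by [write_event_log()].
#' @return An `event_log`.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort_input("empty event log file")
  records <- purrr::map(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$record)) {
      abort_input(sprintf("malformed event-log record at line %d", i),
                  class = "tapbattery_validation_error")
    }
    rec
  })
  kinds <- purrr::map_chr(records, "record")
  if (kinds[1] != "header") {
    abort_input("event log must start with a header record",
                class = "tapbattery_validation_error")
  }
  header <- records[[1]]
  schedule <- NULL
  if (!is.null(header$schedule)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(header$schedule, auto_unbox = TRUE,
                                digits = NA, na = "null"), tmp)
    schedule <- read_schedule(tmp)
  }
  to_tbl <- function(recs, cols) {
    dplyr::bind_rows(purrr::map(recs, function(r) {
      r$record <- NULL
      tibble::as_tibble(purrr::map(r, ~ if (is.null(.x)) NA else .x))
    }))[, cols]
  }
  events <- to_tbl(records[kinds == "event"],
                   c("timestamp_ms", "kind", "key", "trial_index", "task"))
  events$timestamp_ms <- as.integer(events$timestamp_ms)
  events$trial_index <- as.integer(events$trial_index)
  if (is.unsorted(events$timestamp_ms)) {
    abort_input("event log timestamps must be non-decreasing",
                class = "tapbattery_validation_error")
  }
  outcomes <- to_tbl(records[kinds == "outcome"],
                     c("task", "trial_index", "block_index", "sequence_index",
                       "is_target", "congruent", "responded", "response_key",
                       "rt_ms", "classification", "n_suppressed_taps"))
  for (col in c("trial_index", "block_index", "sequence_index", "rt_ms",
                "n_suppressed_taps")) {
    outcomes[[col]] <- as.integer(outcomes[[col]])
  }
  structure(
    list(session_id = header$session_id, seed = header$seed,
         schedule = schedule, events = events, outcomes = outcomes),
    class = "event_log"
  )
}

#' Read a usability cohort from CSV
#'
#' Expects one row per participant with columns `id, age, sex,
#' education_years, handedness, region, moca` and either `sus` or
#' `sus_q1`..`sus_q10`. Range violations are reported with their row number.
#'
#' @param path CSV file path.
#' @return A participant tibble ready for [analyze_cohort()].
#' @export
read_cohort <- function(path) {
  table <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  items <- paste0("sus_q", 1:10)
  if (all(items %in% names(table))) {
    for (it in items) {
      bad <- which(is.na(table[[it]]) | table[[it]] < 1 | table[[it]] > 5)
      if (length(bad)) {
        abort_input(sprintf("cohort CSV: `%s` out of [1, 5] at row %d",
                            it, bad[1]),
                    class = "tapbattery_validation_error")
      }
    }
  } else if (!"sus" %in% names(table)) {
    abort_input("cohort CSV needs `sus` or `sus_q1`..`sus_q10` columns",
                class = "tapbattery_validation_error")
  }
  if ("sus" %in% names(table)) {
    bad <- which(is.na(table$sus) | table$sus < 0 | table$sus > 100)
    if (length(bad)) {
      abort_input(sprintf("cohort CSV: `sus` out of [0, 100] at row %d", bad[1]),
                  class = "tapbattery_validation_error")
    }
  }
  if ("moca" %in% names(table)) {
    bad <- which(!is.na(table$moca) & (table$moca < 0 | table$moca > 30))
    if (length(bad)) {
      abort_input(sprintf("cohort CSV: `moca` out of [0, 30] at row %d", bad[1]),
                  class = "tapbattery_validation_error")
    }
  }
  table
}

#' Write a usability cohort to CSV
#'
#' @param table Participant tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Write a battery report to CSV
#'
#' One row per task with all score fields, followed by a `battery` summary
#' row carrying completion and total duration.
#'
#' @param report A `battery_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "battery_report"))
  rows <- dplyr::bind_cols(
    tibble::tibble(session_id = report$session_id), report$scores
  )
  summary_row <- tibble::tibble(
    session_id = report$session_id, task = "battery",
    n_trials = sum(report$scores$n_trials),
    complete = report$complete,
    total_duration_min = report$total_duration_min
  )
  out <- dplyr::bind_rows(rows, summary_row)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a battery report CSV back into tibble form
#'
#' @param path Path written by [write_report()].
#' @return Tibble with one row per task plus the battery summary row.
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
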