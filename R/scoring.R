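# Automated scoring.
#
# All scores are pure functions of the outcome tibble an engine run emits.
# Reaction-time aggregates use hits only; no outlier trimming is applied by
# default (the engine already rules out pre-onset artefacts), but optional
# trim bounds are available.

score_schema <- function(task, n_trials) {
  tibble::tibble(
    task = task, n_trials = n_trials, n_responded = NA_integer_,
    mean_rt_ms = NA_real_, median_rt_ms = NA_real_,
    n_omissions = NA_integer_, n_false_alarms = NA_integer_,
    n_wrong_key = NA_integer_, n_correct_rejections = NA_integer_,
    accuracy = NA_real_,
    interference_effect_ms = NA_real_, interference_error_cost = NA_real_
  )
}

count_class <- function(outcomes, what) sum(outcomes$classification == what)

hit_rts <- function(outcomes, rt_trim_ms) {
  rts <- outcomes$rt_ms[outcomes$classification == "hit"]
  if (!is.null(rt_trim_ms)) {
    rts <- rts[rts >= rt_trim_ms[1] & rts <= rt_trim_ms[2]]
  }
  rts
}

check_task <- function(outcomes, task) {
  if (nrow(outcomes) == 0 || !all(outcomes$task == task)) {
    abort_input(sprintf("outcomes must all come from the %s task", task),
                class = "tapbattery_integrity_error")
  }
}

#' Score the simple visual reaction time task
#'
#' Mean and median reaction time over responded trials plus the omission
#' count. With zero responded trials the RT fields are `NA`, not an error.
#'
#' @param outcomes Outcome tibble (rows of one task) from [run_session()].
#' @param rt_trim_ms Optional length-2 bounds (ms); hits outside are dropped
#'   from RT aggregates. Default `NULL`: no trimming.
#' @return One-row score tibble of class `task_score`.
#' @export
score_svrt <- function(outcomes, rt_trim_ms = NULL) {
  check_task(outcomes, "svrt")
  rts <- hit_rts(outcomes, rt_trim_ms)
  out <- score_schema("svrt", nrow(outcomes))
  out$n_responded <- sum(outcomes$responded)
  out$mean_rt_ms <- if (length(rts)) mean(rts) else NA_real_
  out$median_rt_ms <- if (length(rts)) stats::median(rts) else NA_real_
  out$n_omissions <- count_class(outcomes, "omission")
  new_task_score(out)
}

#' Score the Go/No-Go task
#'
#' RT aggregates over hits; omissions counted on targets, false alarms on
#' non-targets; accuracy is the fraction of trials answered per the rule
#' (hits plus correct rejections).
#'
#' @inheritParams score_svrt
#' @return One-row score tibble of class `task_score`.
#' @export
score_gonogo <- function(outcomes, rt_trim_ms = NULL) {
  check_task(outcomes, "gonogo")
  rts <- hit_rts(outcomes, rt_trim_ms)
  out <- score_schema("gonogo", nrow(outcomes))
  out$n_responded <- sum(outcomes$responded)
  out$mean_rt_ms <- if (length(rts)) mean(rts) else NA_real_
  out$median_rt_ms <- if (length(rts)) stats::median(rts) else NA_real_
  out$n_omissions <- count_class(outcomes, "omission")
  out$n_false_alarms <- count_class(outcomes, "false_alarm")
  out$n_correct_rejections <- count_class(outcomes, "correct_rejection")
  out$accuracy <- (count_class(outcomes, "hit") +
                     count_class(outcomes, "correct_rejection")) / nrow(outcomes)
  new_task_score(out)
}

#' Score the visual recognition task
#'
#' Accuracy is the fraction of probes answered correctly (a hit is either a
#' "yes" to a seen image or a "no" to a distractor). Per-sequence accuracies
#' are kept in the `by_sequence` attribute.
#'
#' @inheritParams score_svrt
#' @param sequences The `vr_sequences` tibble of the schedule, used to check
#'   probe/outcome alignment.
#' @return One-row score tibble of class `task_score`.
#' @export
score_vr <- function(outcomes, sequences, rt_trim_ms = NULL) {
  check_task(outcomes, "visual_recognition")
  if (nrow(outcomes) != sum(sequences$n_probes)) {
    abort_input("probe/outcome misalignment: outcome rows do not match the scheduled probes",
                class = "tapbattery_integrity_error")
  }
  rts <- hit_rts(outcomes, rt_trim_ms)
  out <- score_schema("visual_recognition", nrow(outcomes))
  out$n_responded <- sum(outcomes$responded)
  out$mean_rt_ms <- if (length(rts)) mean(rts) else NA_real_
  out$median_rt_ms <- if (length(rts)) stats::median(rts) else NA_real_
  out$n_omissions <- count_class(outcomes, "omission")
  out$n_false_alarms <- count_class(outcomes, "false_alarm")
  out$n_wrong_key <- count_class(outcomes, "wrong_key")
  out$accuracy <- count_class(outcomes, "hit") / nrow(outcomes)
  by_seq <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$sequence_index),
    accuracy = mean(.data$classification == "hit"), .groups = "drop"
  )
  attr(out, "by_sequence") <- by_seq
  new_task_score(out)
}

# Shared congruency contrast: mean hit RT and error rate, incongruent minus
# congruent. Error = any non-hit outcome on a response trial.
congruency_contrast <- function(outcomes, incongruent, rt_trim_ms) {
  rt_of <- function(rows) {
    rts <- hit_rts(rows, rt_trim_ms)
    if (length(rts)) mean(rts) else NA_real_
  }
  err_of <- function(rows) mean(rows$classification != "hit")
  inc <- outcomes[incongruent, ]
  con <- outcomes[!incongruent, ]
  list(
    effect_ms = rt_of(inc) - rt_of(con),
    error_cost = err_of(inc) - err_of(con)
  )
}

#' Score the Simon task
#'
#' The interference effect is the mean hit RT on incongruent trials minus
#' congruent trials; the error cost is the corresponding error-rate
#' difference. A congruency level with zero hits leaves the effect `NA` with
#' a warning.
#'
#' @inheritParams score_svrt
#' @return One-row score tibble of class `task_score` with
#'   `interference_effect_ms` and `interference_error_cost`.
#' @export
score_simon <- function(outcomes, rt_trim_ms = NULL) {
  check_task(outcomes, "simon")
  if (length(unique(outcomes$congruent)) < 2) {
    abort_input("Simon outcomes must contain both congruency levels",
                class = "tapbattery_integrity_error")
  }
  rts <- hit_rts(outcomes, rt_trim_ms)
  out <- score_schema("simon", nrow(outcomes))
  out$n_responded <- sum(outcomes$responded)
  out$mean_rt_ms <- if (length(rts)) mean(rts) else NA_real_
  out$median_rt_ms <- if (length(rts)) stats::median(rts) else NA_real_
  out$n_omissions <- count_class(outcomes, "omission")
  out$n_wrong_key <- count_class(outcomes, "wrong_key")
  out$accuracy <- count_class(outcomes, "hit") / nrow(outcomes)
  contrast <- congruency_contrast(outcomes, !outcomes$congruent, rt_trim_ms)
  if (is.na(contrast$effect_ms)) {
    rlang::warn("a congruency level has zero hits; interference effect undefined")
  }
  out$interference_effect_ms <- contrast$effect_ms
  out$interference_error_cost <- contrast$error_cost
  new_task_score(out)
}

#' Score the interference task
#'
#' The baseline pools the two colour-matching blocks (0 and 1); the
#' interference condition is the reversed-rule block 2. Effect and error
#' cost are computed as in [score_simon()].
#'
#' @inheritParams score_svrt
#' @param baseline `"pooled"` (blocks 0--1, default) or `"first"` (block 0
#'   only).
#' @return One-row score tibble of class `task_score`.
#' @export
score_interference <- function(outcomes, rt_trim_ms = NULL,
                               baseline = c("pooled", "first")) {
  baseline <- match.arg(baseline)
  check_task(outcomes, "interference")
  if (!all(0:2 %in% outcomes$block_index)) {
    abort_input("interference outcomes must span all three blocks",
                class = "tapbattery_integrity_error")
  }
  if (baseline == "first") {
    outcomes <- outcomes[outcomes$block_index != 1L, ]
  }
  rts <- hit_rts(outcomes, rt_trim_ms)
  out <- score_schema("interference", nrow(outcomes))
  out$n_responded <- sum(outcomes$responded)
  out$mean_rt_ms <- if (length(rts)) mean(rts) else NA_real_
  out$median_rt_ms <- if (length(rts)) stats::median(rts) else NA_real_
  out$n_omissions <- count_class(outcomes, "omission")
  out$n_wrong_key <- count_class(outcomes, "wrong_key")
  out$accuracy <- count_class(outcomes, "hit") / nrow(outcomes)
  contrast <- congruency_contrast(outcomes, outcomes$block_index == 2L,
                                  rt_trim_ms)
  out$interference_effect_ms <- contrast$effect_ms
  out$interference_error_cost <- contrast$error_cost
  new_task_score(out)
}

new_task_score <- function(x) {
  class(x) <- c("task_score", class(x))
  x
}

#' Score one task of an outcome tibble by name
#'
#' @param outcomes Outcome tibble possibly spanning several tasks.
#' @param task Task identifier (see [task_kinds()]).
#' @param sequences `vr_sequences` tibble, required for
#'   `"visual_recognition"`.
#' @param rt_trim_ms Optional RT trim bounds passed through.
#' @return One-row `task_score` tibble.
#' @export
score_task <- function(outcomes, task, sequences = NULL, rt_trim_ms = NULL) {
  rows <- outcomes[outcomes$task == task, ]
  switch(task,
    svrt = score_svrt(rows, rt_trim_ms),
    gonogo = score_gonogo(rows, rt_trim_ms),
    visual_recognition = score_vr(rows, sequences, rt_trim_ms),
    simon = score_simon(rows, rt_trim_ms),
    interference = score_interference(rows, rt_trim_ms),
    abort_input(sprintf("unknown task `%s`", task))
  )
}

#' Summarise a full battery session
#'
#' Scores every completed task of a session and reports completion and total
#' duration. A session is complete when all five tasks have their scheduled
#' number of outcomes.
#'
#' @param log An `event_log` from [run_session()].
#' @param schedule Optional `battery_schedule`; defaults to the one stored in
#'   the log.
#' @param rt_trim_ms Optional RT trim bounds passed to the task scorers.
#' @return A `battery_report`: list with `session_id`, `scores` (tibble, one
#'   row per scored task), `complete`, and `total_duration_min`.
#' @export
summarize_battery <- function(log, schedule = NULL, rt_trim_ms = NULL) {
  stopifnot(inherits(log, "event_log"))
  schedule <- schedule %||% log$schedule
  outcomes <- log$outcomes
  planned <- dplyr::count(schedule$trials, .data$task)
  actual <- dplyr::count(outcomes, .data$task)
  complete <- nrow(outcomes) > 0 &&
    isTRUE(all.equal(planned[order(planned$task), ],
                     actual[order(actual$task), ], check.attributes = FALSE))
  present <- intersect(task_kinds(), unique(outcomes$task))
  scores <- dplyr::bind_rows(purrr::map(
    present, ~ score_task(outcomes, .x, sequences = schedule$vr_sequences,
                          rt_trim_ms = rt_trim_ms)
  ))
  duration <- if (nrow(log$events)) {
    (max(log$events$timestamp_ms) - min(log$events$timestamp_ms)) / 60000
  } else {
    0
  }
  structure(
    list(session_id = log$session_id, scores = scores, complete = complete,
         total_duration_min = duration),
    class = "battery_report"
  )
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("<battery_report> %s: complete=%s, %.1f min\n",
              x$session_id, x$complete, x$total_duration_min))
  print(x$scores)
  invisible(x)
}

#' Tidy a battery report into per-task rows
#'
#' @param x A `battery_report`.
#' @param ... Unused.
#' @return The per-task score tibble with the session id prepended.
#' @exportS3Method generics::tidy
tidy.battery_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(session_id = x$session_id), x$scores)
}

#' One-row summary of a battery report
#'
#' @param x A `battery_report`.
#' @param ... Unused.
#' @return One-row tibble: session id, completion, duration, grand mean RT
#'   and total error count.
#' @exportS3Method generics::glance
glance.battery_report <- function(x, ...) {
  tibble::tibble(
    session_id = x$session_id,
    complete = x$complete,
    total_duration_min = x$total_duration_min,
    n_tasks = nrow(x$scores),
    mean_rt_ms = mean(x$scores$mean_rt_ms, na.rm = TRUE),
    n_errors = sum(x$scores$n_omissions, x$scores$n_false_alarms,
                   x$scores$n_wrong_key, na.rm = TRUE)
  )
}

#' Plot the per-task summary of a battery report
#'
#' @param object A `battery_report`.
#' @param ... Unused.
#' @return A ggplot: mean hit RT per task with error counts annotated.
#' @exportS3Method ggplot2::autoplot
autoplot.battery_report <- function(object, ...) {
  df <- object$scores
  df$task <- factor(df$task, levels = task_kinds())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$mean_rt_ms)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("om %d | fa %s | wk %s", .data$n_omissions,
                      .data$n_false_alarms, .data$n_wrong_key)
    ), vjust = -0.4, size = 3, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "mean hit RT (ms)",
                  title = sprintf("Session %s", object$session_id)) +
    ggplot2::theme_minimal()
}
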