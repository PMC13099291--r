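svrt_schedule <- function(n = 3, seed = 1) {
  cfg <- default_config(svrt_n_trials = n)
  as_battery_schedule(generate_svrt_schedule(cfg, seed), cfg, seed)
}

tap_at <- function(ts, key = "stimulus_area") {
  tibble::tibble(timestamp_ms = as.integer(ts), key = key)
}

test_that("pre-onset taps are ignored but counted, never scored", {
  sched <- svrt_schedule(2)
  onset <- sched$trials$onset_ms[1]
  log <- run_session(sched, tap_at(c(onset - 50, onset + 300)))
  out <- log$outcomes[1, ]
  expect_true(out$responded)
  expect_equal(out$rt_ms, 300L)
  expect_equal(out$classification, "hit")
  expect_equal(out$n_suppressed_taps, 1L)
  # pre-onset immunity: no outcome ever has a negative reaction time
  expect_true(all(is.na(log$outcomes$rt_ms) | log$outcomes$rt_ms >= 0))
})

test_that("no tap inside the window is an omission (or correct rejection)", {
  sched <- svrt_schedule(3)
  log <- run_session(sched, tap_at(integer(0)))
  expect_equal(log$outcomes$classification, rep("omission", 3))
  expect_true(all(is.na(log$outcomes$rt_ms)))

  cfg <- default_config(gonogo_n_trials = 10)
  gsched <- as_battery_schedule(generate_gonogo_schedule(cfg, 1), cfg, 1)
  glog <- run_session(gsched, tap_at(integer(0)))
  expect_equal(
    glog$outcomes$classification,
    ifelse(gsched$trials$is_target, "omission", "correct_rejection")
  )
})

test_that("double taps never answer the current or the next stimulus", {
  sched <- svrt_schedule(2)
  on1 <- sched$trials$onset_ms[1]
  log <- run_session(sched, tap_at(c(on1 + 300, on1 + 380)))
  expect_equal(log$outcomes$rt_ms[1], 300L)
  expect_equal(log$outcomes$n_suppressed_taps[1], 1L)
  # trial 2 saw no tap of its own: omission, untouched by the double tap
  expect_false(log$outcomes$responded[2])
  expect_equal(log$outcomes$classification[2], "omission")
})

test_that("extra taps inside one trial's window never change later trials", {
  sched <- svrt_schedule(4, seed = 8)
  onsets <- sched$trials$onset_ms
  base_taps <- tap_at(onsets + 250)
  base <- run_session(sched, base_taps)
  # bombard trial 2 with ten extra taps across its window
  extra <- tap_at(sort(c(base_taps$timestamp_ms,
                         onsets[2] + seq(300, 1900, length.out = 10))))
  noisy <- run_session(sched, extra)
  expect_equal(behaviour_of(noisy), behaviour_of(base))
  expect_equal(noisy$outcomes$n_suppressed_taps[2], 10L)
})

test_that("window closure is exclusive: a tap at the boundary is too late", {
  sched <- svrt_schedule(2)
  close1 <- sched$trials$close_ms[1]
  log <- run_session(sched, tap_at(close1))
  expect_equal(log$outcomes$classification[1], "omission")
  # the boundary tap belongs to trial 2's pre-onset zone and is suppressed
  expect_equal(log$outcomes$n_suppressed_taps[2], 1L)
  expect_false(log$outcomes$responded[2])
})

test_that("taps on keys inactive for the task are suppressed, not errors", {
  sched <- svrt_schedule(1)
  onset <- sched$trials$onset_ms[1]
  log <- run_session(sched, tap_at(onset + 200, key = "left"))
  expect_false(log$outcomes$responded[1])
  expect_equal(log$outcomes$n_suppressed_taps[1], 1L)
})

test_that("classification follows each task's response rule", {
  expect_equal(classify_response("gonogo", FALSE, FALSE, NA, TRUE, "stimulus_area"),
               "false_alarm")
  expect_equal(classify_response("gonogo", TRUE, TRUE, "stimulus_area", FALSE, NA),
               "omission")
  expect_equal(classify_response("gonogo", FALSE, FALSE, NA, FALSE, NA),
               "correct_rejection")
  expect_equal(classify_response("simon", TRUE, TRUE, "left", TRUE, "left"), "hit")
  expect_equal(classify_response("simon", TRUE, TRUE, "left", TRUE, "right"),
               "wrong_key")
  # recognition probes compare yes/no with the ground truth
  expect_equal(classify_response("visual_recognition", FALSE, TRUE, "no", TRUE, "no"),
               "hit")
  expect_equal(classify_response("visual_recognition", FALSE, TRUE, "no", TRUE, "yes"),
               "false_alarm")
})

test_that("outcome classes conserve the trial count per task", {
  sched <- generate_battery(default_config(), seed = 21)
  profile <- respondent_profile(double_tap_rate = 0.5, anticipation_rate = 0.5,
                                lapse_rate = 0.1, commission_rate = 0.3,
                                seed = 21)
  log <- simulate_session(sched, profile)
  tally <- dplyr::count(log$outcomes, task, classification)
  per_task <- dplyr::summarise(dplyr::group_by(tally, task), n = sum(n))
  planned <- dplyr::count(sched$trials, task)
  expect_equal(per_task$n[match(planned$task, per_task$task)], planned$n)
  expect_true(all(log$outcomes$rt_ms >= 0, na.rm = TRUE))
  expect_true(all(is.na(log$outcomes$rt_ms) == !log$outcomes$responded))
})

test_that("replay reproduces a session and detects tampering", {
  sched <- generate_battery(default_config(), seed = 4)
  log <- simulate_session(sched, respondent_profile(seed = 4))
  again <- replay(log)
  expect_equal(again$outcomes, log$outcomes)

  # removing one response tap changes exactly the affected trial; pick a
  # trial whose window saw a single tap so the pruning is unambiguous
  taps <- dplyr::filter(log$events, kind == "tap")[, c("timestamp_ms", "key")]
  hit_rows <- which(log$outcomes$responded & log$outcomes$n_suppressed_taps == 0)
  victim <- log$outcomes[hit_rows[5], ]
  victim_ts <- log$schedule$trials$onset_ms[hit_rows[5]] + victim$rt_ms
  pruned <- taps[taps$timestamp_ms != victim_ts, ]
  modified <- run_session(sched, pruned)
  diff_rows <- which(modified$outcomes$classification != log$outcomes$classification |
                       !is.na(modified$outcomes$rt_ms) != !is.na(log$outcomes$rt_ms))
  expect_equal(diff_rows, hit_rows[5])

  corrupted <- log
  corrupted$outcomes$rt_ms[hit_rows[1]] <- corrupted$outcomes$rt_ms[hit_rows[1]] + 5L
  expect_error(replay(corrupted), class = "tapbattery_integrity_error")
})

test_that("malformed tap streams are rejected", {
  sched <- svrt_schedule(2)
  expect_error(run_session(sched, tibble::tibble(timestamp_ms = c(100L, 50L),
                                                 key = "stimulus_area")),
               "non-decreasing")
  expect_error(run_session(sched, tibble::tibble(timestamp_ms = 100L,
                                                 key = "elbow")),
               "unknown tap key")
})
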