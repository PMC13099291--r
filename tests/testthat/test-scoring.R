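constant_svrt_outcomes <- function(n = 35, rt = 300L, responded = TRUE) {
  tibble::tibble(
    task = "svrt", trial_index = seq_len(n) - 1L, block_index = 0L,
    sequence_index = NA_integer_, is_target = TRUE, congruent = NA,
    responded = responded,
    response_key = ifelse(responded, "stimulus_area", NA_character_),
    rt_ms = ifelse(responded, rt, NA_integer_),
    classification = ifelse(responded, "hit", "omission"),
    n_suppressed_taps = 0L
  )
}

test_that("constant and degenerate inputs score analytically", {
  all_resp <- score_svrt(constant_svrt_outcomes())
  expect_equal(all_resp$mean_rt_ms, 300)
  expect_equal(all_resp$median_rt_ms, 300)
  expect_equal(all_resp$n_omissions, 0L)

  none <- score_svrt(constant_svrt_outcomes(responded = FALSE))
  expect_equal(none$n_omissions, 35L)
  expect_true(is.na(none$mean_rt_ms))
  expect_true(is.na(none$median_rt_ms))
})

test_that("go/no-go errors are counted on the right stimulus class", {
  cfg <- default_config()
  sched <- as_battery_schedule(generate_gonogo_schedule(cfg, 1), cfg, 1)

  perfect <- score_gonogo(simulate_session(sched, clean_profile(2))$outcomes)
  expect_equal(perfect$n_false_alarms, 0L)
  expect_equal(perfect$n_omissions, 0L)
  expect_equal(perfect$accuracy, 1)

  all_comm <- score_gonogo(simulate_session(
    sched, clean_profile(2, commission_rate = 1)
  )$outcomes)
  expect_equal(all_comm$n_false_alarms, 35L)

  # commission_rate 0.2 over many seeds: mean false-alarm count ~ 35 * 0.2
  fa <- purrr::map_int(1:100, function(s) {
    log <- simulate_session(sched, clean_profile(s, commission_rate = 0.2))
    score_gonogo(log$outcomes)$n_false_alarms
  })
  expect_equal(mean(fa), 7, tolerance = 1 / 7)
})

test_that("recognition accuracy tracks the response probabilities", {
  cfg <- default_config()
  vr <- generate_vr_schedule(cfg, 1)
  sched <- as_battery_schedule(
    tapbattery:::vr_probe_trials(vr, cfg$response_window_s), cfg, 1
  )
  sched$vr_sequences <- vr

  perfect <- score_vr(simulate_session(sched, clean_profile(1))$outcomes, vr)
  expect_equal(perfect$accuracy, 1)

  acc_at <- function(hit, fa, seeds) {
    purrr::map_dbl(seeds, function(s) {
      log <- simulate_session(sched, clean_profile(s, vr_hit_rate = hit,
                                                   vr_false_alarm_rate = fa))
      score_vr(log$outcomes, vr)$accuracy
    })
  }
  # chance-level responding on balanced probes
  expect_equal(mean(acc_at(0.5, 0.5, 1:30)), 0.5, tolerance = 0.08)
  # hit rate 0.9 / false-alarm rate 0.1: expected accuracy 0.9
  expect_equal(mean(acc_at(0.9, 0.1, 1:30)), 0.9, tolerance = 0.04)

  expect_error(score_vr(simulate_session(sched, clean_profile(1))$outcomes[-1, ], vr),
               class = "tapbattery_integrity_error")
})

simon_outcomes <- function(congruent, classification, rt) {
  n <- length(congruent)
  tibble::tibble(
    task = "simon", trial_index = seq_len(n) - 1L, block_index = 0L,
    sequence_index = NA_integer_, is_target = TRUE, congruent = congruent,
    responded = classification != "omission",
    response_key = ifelse(classification == "omission", NA, "left"),
    rt_ms = as.integer(rt), classification = classification,
    n_suppressed_taps = 0L
  )
}

test_that("Simon contrast is the incongruent-minus-congruent difference", {
  # identical RTs on both levels give a null contrast
  null <- score_simon(simon_outcomes(rep(c(TRUE, FALSE), 10),
                                     rep("hit", 20), rep(400L, 20)))
  expect_equal(null$interference_effect_ms, 0)
  expect_equal(null$interference_error_cost, 0)

  # maximal error cost: all incongruent wrong, all congruent hit
  cls <- ifelse(rep(c(TRUE, FALSE), 10), "hit", "wrong_key")
  maximal <- suppressWarnings(
    score_simon(simon_outcomes(rep(c(TRUE, FALSE), 10), cls, 400L))
  )
  expect_equal(maximal$interference_error_cost, 1)
  expect_warning(
    score_simon(simon_outcomes(rep(c(TRUE, FALSE), 10), cls, 400L)),
    "zero hits"
  )

  expect_error(score_simon(simon_outcomes(rep(TRUE, 10), rep("hit", 10), 400L)),
               class = "tapbattery_integrity_error")

  # parameter recovery: simulated 50 ms effect at 2,000 trials
  cfg <- default_config(simon_n_trials = 2000)
  for (s in 1:3) {
    sched <- as_battery_schedule(generate_simon_schedule(cfg, s), cfg, s)
    log <- simulate_session(sched, clean_profile(s, simon_effect_ms = 50))
    est <- score_simon(log$outcomes)$interference_effect_ms
    expect_lt(abs(est - 50), 10)
  }
})

test_that("interference cost contrasts block 2 against the pooled baseline", {
  cfg <- default_config(interference_total_stimuli = 3000)
  sched <- as_battery_schedule(generate_interference_schedule(cfg, 2), cfg, 2)

  null <- score_interference(simulate_session(
    sched, clean_profile(4, interference_cost_ms = 0)
  )$outcomes)
  expect_lt(abs(null$interference_effect_ms), 15)

  shifted <- score_interference(simulate_session(
    sched, clean_profile(4, interference_cost_ms = 80)
  )$outcomes)
  expect_lt(abs(shifted$interference_effect_ms - 80), 15)

  truncated <- simulate_session(sched, clean_profile(4))$outcomes
  expect_error(score_interference(truncated[truncated$block_index != 2L, ]),
               class = "tapbattery_integrity_error")
})

test_that("aggregates equal a brute-force recomputation on small sessions", {
  cfg <- default_config(svrt_n_trials = 5, gonogo_n_trials = 6,
                        vr_n_sequences = 2, simon_n_trials = 6,
                        interference_total_stimuli = 6)
  sched <- generate_battery(cfg, seed = 17)
  log <- simulate_session(sched, respondent_profile(lapse_rate = 0.2,
                                                    commission_rate = 0.4,
                                                    vr_hit_rate = 0.7,
                                                    vr_false_alarm_rate = 0.3,
                                                    seed = 17))
  for (tk in task_kinds()) {
    rows <- log$outcomes[log$outcomes$task == tk, ]
    oracle <- brute_force_score(rows)
    score <- score_task(log$outcomes, tk, sequences = sched$vr_sequences)
    expect_equal(score$mean_rt_ms, oracle$mean_rt, info = tk)
    expect_equal(score$median_rt_ms, oracle$median_rt, info = tk)
    expect_equal(score$n_omissions, oracle$n_omissions, info = tk)
    if (!is.na(score$n_false_alarms)) {
      expect_equal(score$n_false_alarms, oracle$n_false_alarms, info = tk)
    }
    if (!is.na(score$n_wrong_key)) {
      expect_equal(score$n_wrong_key, oracle$n_wrong_key, info = tk)
    }
  }
})

test_that("scoring is a pure function of the outcomes", {
  cfg <- default_config(simon_n_trials = 40)
  sched <- as_battery_schedule(generate_simon_schedule(cfg, 3), cfg, 3)
  out <- simulate_session(sched, respondent_profile(seed = 3))$outcomes
  expect_identical(score_simon(out), score_simon(out))
})

test_that("battery summary reports completion, duration and round-trips", {
  sched <- generate_battery(default_config(), seed = 9)
  log <- simulate_session(sched, respondent_profile(seed = 9))
  report <- summarize_battery(log)
  expect_true(report$complete)
  expect_equal(nrow(report$scores), 5L)
  expect_lte(report$total_duration_min, 30)

  # a session missing a whole task is flagged incomplete
  partial <- log
  partial$outcomes <- partial$outcomes[partial$outcomes$task != "interference", ]
  pr <- summarize_battery(partial)
  expect_false(pr$complete)
  expect_equal(nrow(pr$scores), 4L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(back$mean_rt_ms[back$task == "svrt"],
               report$scores$mean_rt_ms[report$scores$task == "svrt"])
  expect_equal(nrow(back), 6L) # five tasks + battery summary row

  tidied <- tidy(report)
  expect_equal(nrow(tidied), 5L)
  expect_true(all(tidied$session_id == log$session_id))
  gl <- glance(report)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$complete)
})
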