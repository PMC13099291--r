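# Shared fixtures: everything is generated in code at test time.

default_config <- function(...) battery_config(...)

# A respondent with every stochastic nuisance switched off and no lapses:
# useful when a test needs analytically predictable outcomes.
clean_profile <- function(seed = 1L, ...) {
  defaults <- list(lapse_rate = 0, commission_rate = 0, double_tap_rate = 0,
                   anticipation_rate = 0, vr_hit_rate = 1,
                   vr_false_alarm_rate = 0, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(respondent_profile, args)
}

simulate_session <- function(schedule, profile) {
  run_session(schedule, simulate_taps(schedule, profile))
}

# Behavioural outcome columns: the per-trial response record, excluding the
# n_suppressed_taps diagnostic counter (which by design changes when extra
# taps are injected, while the behaviour must not).
behaviour_of <- function(log) {
  log$outcomes[, c("task", "trial_index", "responded", "response_key",
                   "rt_ms", "classification")]
}

# Brute-force per-task aggregates straight off the outcome rows, written as
# plain loops so they stay independent of the scoring implementation.
brute_force_score <- function(outcomes) {
  rts <- c()
  n_hit <- n_om <- n_fa <- n_wk <- n_cr <- 0L
  for (i in seq_len(nrow(outcomes))) {
    cls <- outcomes$classification[i]
    if (cls == "hit") {
      n_hit <- n_hit + 1L
      rts <- c(rts, outcomes$rt_ms[i])
    }
    if (cls == "omission") n_om <- n_om + 1L
    if (cls == "false_alarm") n_fa <- n_fa + 1L
    if (cls == "wrong_key") n_wk <- n_wk + 1L
    if (cls == "correct_rejection") n_cr <- n_cr + 1L
  }
  list(mean_rt = if (length(rts)) sum(rts) / length(rts) else NA_real_,
       median_rt = if (length(rts)) stats::median(rts) else NA_real_,
       n_hit = n_hit, n_omissions = n_om, n_false_alarms = n_fa,
       n_wrong_key = n_wk, n_correct_rejections = n_cr)
}

# Definitional Spearman coefficient: rank both vectors (average ranks) and
# take the Pearson correlation via stats::cor — the independent oracle.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}
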