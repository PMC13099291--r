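# Trial-schedule generation for the five tasks.
#
# Every generator is a pure function of (config, seed): regeneration with the
# same arguments is byte-identical after serialization. Each task draws from
# its own sub-seed, so changing one task's parameters leaves the others'
# schedules untouched.

# Shared column layout of a trial tibble; every generator fills this schema
# so task schedules can be row-bound into one battery timeline.
trial_tibble <- function(task, n, block_index, onset_delay_s, response_window_s,
                         shape, color, side, is_target, congruent,
                         requires_response, correct_key,
                         sequence_index = NA_integer_, probe_id = NA_character_,
                         display_duration_s = NA_real_) {
  tibble::tibble(
    task = task,
    trial_index = seq_len(n) - 1L,
    block_index = as.integer(block_index),
    onset_delay_s = onset_delay_s,
    response_window_s = response_window_s,
    shape = shape,
    color = color,
    side = side,
    is_target = is_target,
    congruent = congruent,
    requires_response = requires_response,
    correct_key = correct_key,
    sequence_index = as.integer(sequence_index),
    probe_id = probe_id,
    display_duration_s = display_duration_s
  )
}

# Balanced logical vector with round(frac * n) TRUEs, shuffled.
shuffled_flags <- function(n, frac) {
  k <- round(frac * n)
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

#' Generate the simple visual reaction time (sVRT) schedule
#'
#' Each trial shows a blue circle that turns yellow after a random warning
#' interval drawn uniformly from `svrt_interval_range_s`; the participant taps
#' the circle as soon as it changes colour.
#'
#' @param config A [battery_config()].
#' @param seed Integer seed; the task uses its own substream derived from it.
#' @return A tibble with one row per trial (`trial_index`, `onset_delay_s`,
#'   stimulus fields, `correct_key`).
#' @examples
#' nrow(generate_svrt_schedule(battery_config(), 1)) # 35
#' @export
generate_svrt_schedule <- function(config, seed) {
  validate_battery_config(config)
  n <- config$svrt_n_trials
  rng <- config$svrt_interval_range_s
  withr::with_seed(derive_seed(seed, "svrt"), {
    trial_tibble(
      task = "svrt", n = n, block_index = 0L,
      onset_delay_s = stats::runif(n, rng[1], rng[2]),
      response_window_s = config$response_window_s,
      shape = "circle", color = "yellow", side = "center",
      is_target = TRUE, congruent = NA,
      requires_response = TRUE, correct_key = "stimulus_area"
    )
  })
}

#' Generate the Go/No-Go schedule
#'
#' Targets (squares, tap) and non-targets (circles, withhold) appear in a
#' seed-shuffled order at random 4--8 s intervals; the target count is
#' `round(gonogo_target_fraction * gonogo_n_trials)`.
#'
#' @inheritParams generate_svrt_schedule
#' @return A tibble with one row per trial.
#' @export
generate_gonogo_schedule <- function(config, seed) {
  validate_battery_config(config)
  n <- config$gonogo_n_trials
  rng <- config$svrt_interval_range_s # same interval source as sVRT
  withr::with_seed(derive_seed(seed, "gonogo"), {
    target <- shuffled_flags(n, config$gonogo_target_fraction)
    trial_tibble(
      task = "gonogo", n = n, block_index = 0L,
      onset_delay_s = stats::runif(n, rng[1], rng[2]),
      response_window_s = config$response_window_s,
      shape = ifelse(target, "square", "circle"),
      color = "none", side = "center",
      is_target = target, congruent = NA,
      requires_response = target,
      correct_key = ifelse(target, "stimulus_area", NA_character_)
    )
  })
}

# Abstract image-identifier pool per alternate form. Versions A and B index
# the same positions of version-prefixed pools, so the two forms share
# structure exactly while sharing no identifiers.
VR_POOL_SIZE <- 500L

#' Generate the visual recognition sequences
#'
#' Eight sequences of 2 to 8 abstract images (the last length repeats when
#' there are more sequences than distinct lengths), displayed for durations
#' interpolated linearly across `vr_duration_range_s`. After each sequence a
#' probe set mixes every encoded image with ceiling(length / 2) unseen
#' distractors; the participant answers yes/no per probe.
#'
#' @inheritParams generate_svrt_schedule
#' @param version Alternate form, `"A"` or `"B"`; defaults to the config's.
#' @return A tibble with one row per sequence: `sequence_index`, `version`,
#'   `display_duration_s`, and list-columns `encoding_ids`, `probe_ids`,
#'   `probe_truth`.
#' @export
generate_vr_schedule <- function(config, seed, version = config$vr_version) {
  validate_battery_config(config)
  n_seq <- config$vr_n_sequences
  lengths <- pmin(2L + seq_len(n_seq) - 1L, 8L)
  durations <- seq(config$vr_duration_range_s[1], config$vr_duration_range_s[2],
                   length.out = n_seq)
  n_distract <- ceiling(lengths / 2)
  if (sum(lengths + n_distract) > VR_POOL_SIZE) {
    abort_input("image pool exhausted: too many sequences for the identifier pool",
                class = "tapbattery_generation_error")
  }
  # structural draws are version-independent: same seed => same layout
  withr::with_seed(derive_seed(seed, "visual_recognition"), {
    pool <- sample.int(VR_POOL_SIZE)
    taken <- 0L
    rows <- purrr::map(seq_len(n_seq), function(i) {
      enc_idx <- pool[taken + seq_len(lengths[i])]
      taken <<- taken + lengths[i]
      dis_idx <- pool[taken + seq_len(n_distract[i])]
      taken <<- taken + n_distract[i]
      truth <- sample(c(rep(TRUE, lengths[i]), rep(FALSE, n_distract[i])))
      probe_idx <- integer(length(truth))
      probe_idx[truth] <- sample(enc_idx)
      probe_idx[!truth] <- dis_idx
      list(enc = enc_idx, probes = probe_idx, truth = truth)
    })
    id_of <- function(idx) sprintf("%s%03d", version, idx)
    tibble::tibble(
      sequence_index = seq_len(n_seq),
      version = version,
      n_encoding = lengths,
      display_duration_s = durations,
      encoding_ids = purrr::map(rows, ~ id_of(.x$enc)),
      probe_ids = purrr::map(rows, ~ id_of(.x$probes)),
      probe_truth = purrr::map(rows, "truth"),
      n_probes = lengths + n_distract
    )
  })
}

# Expand VR sequences into per-probe trials for the session engine. The first
# probe of a sequence is preceded by the encoding display plus a 1 s pause;
# later probes follow at 0.5 s.
vr_probe_trials <- function(sequences, response_window_s) {
  per_seq <- purrr::pmap(sequences, function(sequence_index, display_duration_s,
                                             probe_ids, probe_truth, n_probes, ...) {
    tibble::tibble(
      block_index = sequence_index - 1L,
      onset_delay_s = c(display_duration_s + 1, rep(0.5, n_probes - 1L)),
      is_target = probe_truth,
      probe_id = probe_ids,
      sequence_index = sequence_index,
      display_duration_s = display_duration_s
    )
  })
  flat <- dplyr::bind_rows(per_seq)
  trial_tibble(
    task = "visual_recognition", n = nrow(flat),
    block_index = flat$block_index,
    onset_delay_s = flat$onset_delay_s,
    response_window_s = response_window_s,
    shape = "image_set", color = "none", side = "center",
    is_target = flat$is_target, congruent = NA,
    requires_response = TRUE,
    correct_key = ifelse(flat$is_target, "yes", "no"),
    sequence_index = flat$sequence_index,
    probe_id = flat$probe_id,
    display_duration_s = flat$display_duration_s
  )
}

# Fixed colour-to-key mapping of the Simon task: green -> left, red -> right.
simon_key_for <- function(color) ifelse(color == "green", "left", "right")

# Self-paced tasks use a short fixed inter-trial interval.
SELF_PACED_ITI_S <- 1.0

#' Generate the Simon task schedule
#'
#' A red or green square appears left or right of centre; the response key is
#' dictated by colour alone (left for green, right for red). A trial is
#' congruent when the stimulus side matches the side of its correct key;
#' `round(simon_congruent_fraction * n)` trials are congruent, and both
#' colours appear on both sides.
#'
#' @inheritParams generate_svrt_schedule
#' @return A tibble with one row per trial including `congruent` and
#'   `correct_key`.
#' @export
generate_simon_schedule <- function(config, seed) {
  validate_battery_config(config)
  n <- config$simon_n_trials
  withr::with_seed(derive_seed(seed, "simon"), {
    congruent <- shuffled_flags(n, config$simon_congruent_fraction)
    color <- character(n)
    # balance colours within each congruency level so both colours occur on
    # both sides whenever the level has >= 2 trials
    for (lv in c(TRUE, FALSE)) {
      idx <- which(congruent == lv)
      color[idx] <- sample(rep_len(c("green", "red"), length(idx)))
    }
    key <- simon_key_for(color)
    side <- ifelse(congruent, key, ifelse(key == "left", "right", "left"))
    trial_tibble(
      task = "simon", n = n, block_index = 0L,
      onset_delay_s = SELF_PACED_ITI_S,
      response_window_s = config$response_window_s,
      shape = "colored_square", color = color, side = side,
      is_target = TRUE, congruent = congruent,
      requires_response = TRUE, correct_key = key
    )
  })
}

#' Generate the interference task schedule
#'
#' Three blocks of equal size. Block 0: green key left, red key right,
#' respond to the square's colour on the matching key. Block 1: the key
#' layout is mirrored (red left, green right), same colour-matching rule.
#' Block 2: the original layout returns but the rule reverses — tap left for
#' red and right for green. Every trial row carries its block's correct key,
#' so the session engine stays stateless across blocks.
#'
#' @inheritParams generate_svrt_schedule
#' @return A tibble with one row per trial; `congruent` is `TRUE` in the
#'   colour-matching blocks 0--1 and `FALSE` in the reversed-rule block 2.
#' @export
generate_interference_schedule <- function(config, seed) {
  validate_battery_config(config)
  total <- config$interference_total_stimuli
  per_block <- total %/% 3L
  withr::with_seed(derive_seed(seed, "interference"), {
    blocks <- purrr::map(0:2, function(b) {
      color <- sample(rep_len(c("green", "red"), per_block))
      key <- if (b == 2L) {
        ifelse(color == "red", "left", "right") # reversed rule
      } else if (b == 1L) {
        ifelse(color == "green", "right", "left") # mirrored key layout
      } else {
        ifelse(color == "green", "left", "right")
      }
      tibble::tibble(block_index = b, color = color, correct_key = key)
    })
    flat <- dplyr::bind_rows(blocks)
    trial_tibble(
      task = "interference", n = total,
      block_index = flat$block_index,
      onset_delay_s = SELF_PACED_ITI_S,
      response_window_s = config$response_window_s,
      shape = "colored_square", color = flat$color, side = "center",
      is_target = TRUE, congruent = flat$block_index < 2L,
      requires_response = TRUE, correct_key = flat$correct_key
    )
  })
}

#' Generate the full battery schedule
#'
#' Assembles the five task schedules in battery order (sVRT, Go/No-Go, visual
#' recognition, Simon, interference) onto one absolute millisecond timeline.
#' Deterministic: the same `(config, seed)` pair always yields a schedule
#' whose serialized form is byte-identical.
#'
#' @inheritParams generate_svrt_schedule
#' @return A `battery_schedule`: list with `seed`, `config`, the trial tibble
#'   `trials` (visual-recognition probes expanded to one row each, plus
#'   absolute `trial_open_ms`, `onset_ms`, `close_ms`), and the
#'   `vr_sequences` tibble.
#' @examples
#' sched <- generate_battery(battery_config(), seed = 7)
#' dplyr::count(sched$trials, task)
#' @export
generate_battery <- function(config, seed) {
  validate_battery_config(config)
  vr <- generate_vr_schedule(config, seed)
  trials <- dplyr::bind_rows(
    generate_svrt_schedule(config, seed),
    generate_gonogo_schedule(config, seed),
    vr_probe_trials(vr, config$response_window_s),
    generate_simon_schedule(config, seed),
    generate_interference_schedule(config, seed)
  )
  new_battery_schedule(trials, config = config, seed = seed, vr_sequences = vr)
}

# Attach the absolute timeline and wrap as battery_schedule. Trials are laid
# end to end: a trial opens when the previous one closes, the stimulus comes
# on after onset_delay_s, and the trial closes when its response window ends.
new_battery_schedule <- function(trials, config, seed, vr_sequences = NULL) {
  onset_gap <- as.integer(round(trials$onset_delay_s * 1000))
  window_ms <- as.integer(round(trials$response_window_s * 1000))
  close <- cumsum(onset_gap + window_ms)
  trials$trial_open_ms <- c(0L, close[-length(close)])
  trials$onset_ms <- trials$trial_open_ms + onset_gap
  trials$close_ms <- close
  structure(
    list(seed = as.integer(seed), config = config, trials = trials,
         vr_sequences = vr_sequences),
    class = "battery_schedule"
  )
}

#' Coerce a single-task trial tibble to a runnable schedule
#'
#' Wraps a trial tibble from one of the `generate_*_schedule()` functions so
#' it can be fed to [run_session()] on its own, without the rest of the
#' battery.
#'
#' @param trials A trial tibble.
#' @param config The [battery_config()] the trials came from.
#' @param seed Seed to record on the schedule.
#' @return A `battery_schedule`.
#' @export
as_battery_schedule <- function(trials, config, seed = NA_integer_) {
  new_battery_schedule(trials, config = config, seed = seed)
}

#' @export
print.battery_schedule <- function(x, ...) {
  cat(sprintf("<battery_schedule> seed=%s, %d trials, %.1f min planned\n",
              x$seed, nrow(x$trials), max(x$trials$close_ms) / 60000))
  print(dplyr::count(x$trials, .data$task))
  invisible(x)
}
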