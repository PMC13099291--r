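# Virtual-respondent simulation.
#
# The simulator exists to exercise the engine and scoring end-to-end without
# human data. Reaction times follow an ex-Gaussian (Gaussian plus exponential
# tail), the standard positively-skewed RT model; behavioural lapses,
# commissions, anticipatory taps and double taps are independent Bernoulli
# events. Behaviour draws and nuisance-tap draws come from separate
# substreams of the profile seed, so switching double taps or anticipations
# on and off leaves the underlying responses — and therefore the engine's
# outcomes — bit-identical.

#' Virtual respondent profile
#'
#' Generative parameters of one simulated participant.
#'
#' @param base_rt_ms Gaussian location of the reaction-time distribution (ms).
#' @param rt_sigma_ms Gaussian scale (ms).
#' @param rt_tau_ms Mean of the exponential tail (ms); the ex-Gaussian mean is
#'   `base_rt_ms + rt_tau_ms`.
#' @param lapse_rate Probability of omitting a required response.
#' @param commission_rate Probability of tapping a no-go stimulus.
#' @param simon_effect_ms Mean RT slowing on incongruent Simon trials.
#' @param interference_cost_ms Mean RT slowing in the reversed-rule
#'   interference block.
#' @param vr_hit_rate Probability of answering "yes" to a previously seen
#'   recognition probe.
#' @param vr_false_alarm_rate Probability of answering "yes" to a distractor.
#' @param double_tap_rate Probability that a response is followed by a second
#'   tap 30--120 ms later.
#' @param anticipation_rate Probability of an extra tap up to 500 ms before
#'   stimulus onset.
#' @param seed Integer seed for the respondent's private random streams.
#' @return A validated list of class `respondent_profile`.
#' @examples
#' respondent_profile(simon_effect_ms = 50, seed = 3)
#' @export
respondent_profile <- function(base_rt_ms = 350, rt_sigma_ms = 40,
                               rt_tau_ms = 60, lapse_rate = 0.02,
                               commission_rate = 0.05, simon_effect_ms = 30,
                               interference_cost_ms = 60, vr_hit_rate = 0.9,
                               vr_false_alarm_rate = 0.1,
                               double_tap_rate = 0.05,
                               anticipation_rate = 0.02, seed = 1L) {
  profile <- structure(
    list(base_rt_ms = base_rt_ms, rt_sigma_ms = rt_sigma_ms,
         rt_tau_ms = rt_tau_ms, lapse_rate = lapse_rate,
         commission_rate = commission_rate, simon_effect_ms = simon_effect_ms,
         interference_cost_ms = interference_cost_ms,
         vr_hit_rate = vr_hit_rate, vr_false_alarm_rate = vr_false_alarm_rate,
         double_tap_rate = double_tap_rate,
         anticipation_rate = anticipation_rate, seed = as.integer(seed)),
    class = "respondent_profile"
  )
  for (f in c("lapse_rate", "commission_rate", "vr_hit_rate",
              "vr_false_alarm_rate", "double_tap_rate", "anticipation_rate")) {
    v <- profile[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort_config(f, "must be a probability in [0, 1]")
    }
  }
  for (f in c("base_rt_ms", "rt_sigma_ms", "rt_tau_ms")) {
    if (profile[[f]] <= 0) abort_config(f, "must be positive")
  }
  profile
}

# Ex-Gaussian deviates from pre-drawn standard normal / unit exponential.
ex_gaussian_rt <- function(mu, sigma, tau, z, e) {
  pmax(1, mu + sigma * z + tau * e)
}

#' Simulate a tap stream for a schedule
#'
#' Produces the ordered tap events a virtual respondent with the given
#' profile would emit over the schedule's timeline: one response tap per
#' non-lapsed required trial at onset + ex-Gaussian RT (shifted by
#' `simon_effect_ms` on incongruent Simon trials and by
#' `interference_cost_ms` in the reversed-rule block), commission taps on
#' no-go trials, plus optional pre-onset anticipations and rapid double taps
#' drawn from an independent substream.
#'
#' @param schedule A `battery_schedule`.
#' @param profile A [respondent_profile()].
#' @return Tibble of taps (`timestamp_ms`, `key`) sorted by time,
#'   deterministic under `(schedule, profile$seed)`.
#' @export
simulate_taps <- function(schedule, profile) {
  stopifnot(inherits(schedule, "battery_schedule"),
            inherits(profile, "respondent_profile"))
  trials <- schedule$trials
  n <- nrow(trials)

  beh <- withr::with_seed(derive_seed(profile$seed, "behavior"), {
    list(u_lapse = stats::runif(n), z = stats::rnorm(n), e = stats::rexp(n),
         u_comm = stats::runif(n), u_vr = stats::runif(n))
  })
  noise <- withr::with_seed(derive_seed(profile$seed, "noise"), {
    list(u_ant = stats::runif(n), ant_off = stats::runif(n, 0, 500),
         u_dbl = stats::runif(n), dbl_gap = stats::runif(n, 30, 120))
  })

  mu <- profile$base_rt_ms +
    ifelse(trials$task == "simon" & !trials$congruent,
           profile$simon_effect_ms, 0) +
    ifelse(trials$task == "interference" & trials$block_index == 2L,
           profile$interference_cost_ms, 0)
  rt <- ex_gaussian_rt(mu, profile$rt_sigma_ms, profile$rt_tau_ms,
                       beh$z, beh$e)

  responds <- ifelse(trials$requires_response,
                     beh$u_lapse >= profile$lapse_rate,
                     beh$u_comm < profile$commission_rate)
  vr <- trials$task == "visual_recognition"
  say_yes <- ifelse(trials$is_target,
                    beh$u_vr < profile$vr_hit_rate,
                    beh$u_vr < profile$vr_false_alarm_rate)
  resp_key <- dplyr::case_when(
    vr & say_yes ~ "yes",
    vr & !say_yes ~ "no",
    TRUE ~ trials$correct_key
  )
  resp_key[is.na(resp_key)] <- "stimulus_area" # commission taps on no-go

  resp_ts <- trials$onset_ms + as.integer(round(rt))

  # nuisance taps: anticipations land strictly inside [trial_open, onset),
  # so they can never answer the previous trial; double taps trail a response
  delay_ms <- trials$onset_ms - trials$trial_open_ms
  ant_ts <- trials$onset_ms -
    as.integer(pmax(1, round(pmin(noise$ant_off, delay_ms - 1))))
  has_ant <- noise$u_ant < profile$anticipation_rate
  has_dbl <- responds & noise$u_dbl < profile$double_tap_rate

  taps <- dplyr::bind_rows(
    tibble::tibble(timestamp_ms = resp_ts[responds], key = resp_key[responds]),
    tibble::tibble(timestamp_ms = ant_ts[has_ant], key = resp_key[has_ant]),
    tibble::tibble(timestamp_ms = resp_ts[has_dbl] +
                     as.integer(round(noise$dbl_gap[has_dbl])),
                   key = resp_key[has_dbl])
  )
  dplyr::arrange(taps, .data$timestamp_ms)
}

#' Simulate a cohort of participants
#'
#' Draws `n` synthetic participants — demographics matched to the usability
#' study's sample (ages 21--90, education 5--24 years, MoCA 19--30,
#' predominantly right-handed northern residents) and SUS scores allocated to
#' the marginal / good / excellent bands in fixed proportions (default
#' 20/20/60%, giving exactly 16/16/48 at n = 80) — and optionally plays a
#' full battery session per participant through the engine.
#'
#' @param n Number of participants.
#' @param config A [battery_config()] used for the sessions.
#' @param seed Master seed.
#' @param sus_props Length-3 proportions of the marginal (<= 67), good
#'   (68--84) and excellent (>= 85) SUS bands; band counts are deterministic
#'   (`round(n * p)`, remainder to the largest band).
#' @param sessions If `TRUE` (default), simulate and run one battery session
#'   per participant; if `FALSE`, return only the participant table.
#' @return List with `participants` (tibble: id, age, sex, education_years,
#'   handedness, region, moca, sus, sus_q1..sus_q10, sus_category) and
#'   `logs` (list of `event_log`, or `NULL` when `sessions = FALSE`).
#' @examples
#' cohort <- simulate_cohort(10, sessions = FALSE, seed = 1)
#' table(cohort$participants$sus_category)
#' @export
simulate_cohort <- function(n, config = battery_config(), seed = 1L,
                            sus_props = c(0.2, 0.2, 0.6), sessions = TRUE) {
  if (n < 1) abort_config("n", "must be a positive count")
  if (length(sus_props) != 3 || any(sus_props < 0) ||
      abs(sum(sus_props) - 1) > 1e-8) {
    abort_config("sus_props", "must be three non-negative proportions summing to 1")
  }
  participants <- withr::with_seed(derive_seed(seed, "cohort"), {
    age <- round(rtrunc_norm(n, 40.75, 17.72, 21, 90))
    edu <- round(rtrunc_norm(n, 15.23, 3.2, 5, 24))
    moca <- round(rtrunc_norm(n, 28.45, 1.72, 19, 30))
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(47, 33) / 80)
    hand <- sample(c("R", "L"), n, replace = TRUE, prob = c(74, 6) / 80)
    region <- sample(c("north", "center", "south"), n, replace = TRUE,
                     prob = c(71, 3, 6) / 80)
    counts <- round(n * sus_props)
    counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
    category <- sample(rep(c("marginal", "good", "excellent"), counts))
    sus <- purrr::map_dbl(category, function(cat) {
      pool <- switch(cat,
        marginal = seq(40, 65, by = 2.5),
        good = seq(67.5, 82.5, by = 2.5),
        excellent = seq(85, 100, by = 2.5)
      )
      sample(pool, 1)
    })
    items <- t(vapply(sus, sus_items_for_score, integer(10)))
    colnames(items) <- paste0("sus_q", 1:10)
    dplyr::bind_cols(
      tibble::tibble(
        id = sprintf("P%03d", seq_len(n)), age = age, sex = sex,
        education_years = edu, handedness = hand, region = region,
        moca = moca, sus = sus, sus_category = category
      ),
      tibble::as_tibble(items)
    )
  })
  logs <- NULL
  if (sessions) {
    profile_seeds <- withr::with_seed(derive_seed(seed, "profiles"),
                                      sample.int(2^31 - 1, n))
    base_rts <- withr::with_seed(derive_seed(seed, "base_rt"),
                                 rtrunc_norm(n, 350, 40, 250, 600))
    schedule <- generate_battery(config, seed)
    logs <- purrr::map(seq_len(n), function(i) {
      profile <- respondent_profile(base_rt_ms = base_rts[i],
                                    seed = profile_seeds[i])
      log <- run_session(schedule, simulate_taps(schedule, profile),
                         session_id = participants$id[i])
      log
    })
  }
  list(participants = participants, logs = logs)
}

# Construct 10 Likert ratings (1-5) whose SUS score equals `score`.
# Adjusted contributions (0-4 each) must sum to score / 2.5; spread the total
# evenly and push the remainder one unit at a time.
sus_items_for_score <- function(score) {
  total <- as.integer(round(score / 2.5))
  adj <- rep(total %/% 10L, 10L)
  rem <- total - sum(adj)
  if (rem > 0) adj[seq_len(rem)] <- adj[seq_len(rem)] + 1L
  ratings <- integer(10)
  odd <- seq(1, 9, by = 2)
  ratings[odd] <- adj[odd] + 1L      # odd items score rating - 1
  ratings[-odd] <- 5L - adj[-odd]    # even items score 5 - rating
  ratings
}
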