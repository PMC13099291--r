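---
title: "Methods: schedule generation, the touch-input contract, simulation and the usability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: schedule generation, the touch-input contract, simulation and the usability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapbattery)
```

`tapbattery` is a headless re-implementation of a tablet cognitive
screening battery: everything that matters scientifically — the trial
timeline, the touch-input rules, the scored quantities, the usability
statistics — is expressed as seeded, pure functions over tibbles, so every
contract can be tested without a device or a participant. This vignette
documents the models and the decisions behind them.

## The battery and its schedule model

A battery is five tasks laid end to end on one absolute millisecond
timeline. Every trial is one row: it *opens* when the previous trial
closes, its stimulus comes on after `onset_delay_s`, and it *closes* when
the response window ends. Laying the window into the timeline makes the
engine a pure function of (schedule, tap stream) with no hidden state.

Tunable parameters (all in `battery_config()`):

| parameter | default | unit | why |
|---|---|---|---|
| `svrt_n_trials` | 35 | trials | deployed battery size |
| `svrt_interval_range_s` | 4–8 | s | uniform warning interval; also used for Go/No-Go |
| `gonogo_n_trials` | 70 | trials | deployed battery size |
| `gonogo_target_fraction` | 0.5 | — | symmetric design maximises both RT and inhibition trials |
| `vr_n_sequences` | 8 | sequences | deployed battery size |
| `vr_duration_range_s` | 2.5–10 | s | display duration, linear across sequences |
| `simon_n_trials` | 20 | trials | ~20 self-paced trials fit the task's one-minute budget |
| `simon_congruent_fraction` | 0.5 | — | balanced congruency contrast |
| `interference_total_stimuli` | 30 | stimuli | total across the three blocks, split 10/10/10 |
| `response_window_s` | 2.0 | s | no tap inside the window = omission |

Three of these deserve justification because the battery's printed
description underdetermines them:

* **Interference totals.** "30 stimuli" is read as the total across all
  three blocks (10 each), not per block: the figure follows the three-block
  description and thirty short self-paced trials are what fits the task's
  ~2-minute duration. The total must be divisible by 3.
* **Recognition sequence lengths.** Eight sequences but only seven distinct
  lengths between 2 and 8: lengths run (2,3,4,5,6,7,8,8), i.e. the final
  length repeats. Probe sets contain every encoded image plus
  ⌈length/2⌉ unseen distractors, making the probe count non-decreasing in
  sequence length, as required of a memory load that grows with the list.
* **Go/No-Go target share and intervals.** The target fraction defaults to
  one half, and the inter-stimulus intervals reuse the sVRT 4–8 s uniform
  range; at the 6 s midpoint this reproduces the task's published 7-minute
  planned duration (70 × 6 s).

The Simon and interference tasks are self-paced; a fixed 1.0 s inter-trial
interval is used, which puts the full battery at ≈ 20 minutes — inside the
20–30 minute range a real session takes.

**Randomness.** One integer seed per battery. Each task draws from its own
substream (a deterministic hash of the seed and the task name), so editing
one task's parameters never perturbs another task's draws, and regenerating
with the same `(config, seed)` is byte-identical after serialization.

## The touch-input contract

The engine enforces the input rules that make tablet reaction times
trustworthy:

1. Response keys are inactive before stimulus onset; a pre-onset tap is
   logged, counted in `n_suppressed_taps`, and never scored.
2. The first valid in-window tap is *the* response; every later tap in the
   same trial is suppressed.
3. A tap belongs to exactly one trial — the one whose `[open, close)`
   interval contains it — so no tap can ever carry into a later trial. A
   rapid double tap therefore cannot register as a response to the next
   stimulus, the failure mode that historically produced impossibly fast
   (< 100 ms, pre-onset) reaction times.
4. The window is half-open: a tap exactly at `onset + response_window` is
   too late (omission). Ties break conservatively against the response.
5. Taps on keys undefined for the task (stray touches) are suppressed, not
   errors.

`replay()` re-runs a stored event log through the engine and insists on
identical outcomes — the regression harness for the contract.

## The virtual respondent

The simulator is a test harness, not a cognition model: it produces tap
streams with controlled psychometric structure so parameter recovery can be
verified end to end.

* **Reaction times** are ex-Gaussian — Gaussian(μ = `base_rt_ms`,
  σ = `rt_sigma_ms`) plus an exponential tail with mean `rt_tau_ms`
  (defaults 350/40/60 ms, so the mean RT is 410 ms). The ex-Gaussian is the
  standard positively skewed RT model, and its skew is what gives the
  normality screen non-trivial data. Simulated RTs are floored at 1 ms.
* **Errors**: omissions with probability `lapse_rate`, no-go commissions
  with `commission_rate`, recognition answers from `vr_hit_rate` /
  `vr_false_alarm_rate`. Incongruent Simon trials add `simon_effect_ms` to
  μ; the reversed-rule block adds `interference_cost_ms`.
* **Nuisance taps**: anticipations land uniformly up to 500 ms before
  onset (clamped inside the trial's own pre-onset zone) and double taps
  trail a response by 30–120 ms. Crucially these are drawn from a
  *separate* substream of the profile seed, so a profile with
  `double_tap_rate = 1` emits exactly the same responses as one with 0 —
  the engine must then produce identical behavioural outcomes, which is the
  debounce-neutrality regression (the `n_suppressed_taps` diagnostic
  necessarily differs, so equality is asserted on the behavioural fields:
  responded, key, RT, classification).

**The synthetic cohort** emulates the usability study's sample: 80
participants, ages from a truncated normal 40.75 ± 17.72 on [21, 90],
education 15.23 ± 3.2 on [5, 24] years, MoCA 28.45 ± 1.72 on [19, 30],
sex 47F/33M, handedness 74R/6L and region 71/3/6 as sampling weights. SUS
band membership (marginal ≤ 67 / good 68–84 / excellent ≥ 85) is allocated
with *deterministic* counts — `round(n × p)` per band at the default
20/20/60% proportions, i.e. exactly 16/16/48 at n = 80 — because the band
composition is a study condition, not a quantity to estimate; scores are
then drawn uniformly from the valid multiples of 2.5 inside each band, and
ten Likert items consistent with each score are synthesised. SUS is
generated independently of the covariates, so the expected correlations are
null. What the generator does **not** emulate: real RT autocorrelation and
fatigue drifts, practice effects, age-dependent slowing, or any genuine
usability–demographics dependence. Passing tests therefore demonstrate the
*pipeline's* correctness (recovery of whatever structure was simulated),
not claims about real populations.

## Scoring decisions

* RT aggregates (mean, median) use **hits only**; wrong-key and
  false-alarm RTs are excluded, per standard practice.
* **No outlier trimming** by default: the engine already makes pre-onset
  artefacts impossible, and any floor/ceiling would be a further analytic
  choice; optional `rt_trim_ms` bounds are available.
* The Simon effect is `mean RT(incongruent hits) − mean RT(congruent
  hits)`; the error cost is the corresponding error-rate difference. A
  congruency level with zero hits yields `NA` with a warning rather than an
  error.
* The interference baseline pools blocks 0–1 (both colour-matching);
  `baseline = "first"` restricts it to block 0 for sensitivity analyses.
* Reports export to CSV (one row per task plus a battery summary row); the
  open format replaces spreadsheet export.

## The usability analysis

* **SUS** uses the canonical scoring (odd items − 1, even items
  5 − rating, × 2.5), forced to the 0–100 grid of multiples of 2.5.
* **Banding** at ≤ 67 / 68–84 / ≥ 85. The only representable score strictly
  between the bands is 67.5, which maps to "good".
* **Normality screen**: adjusted Fisher–Pearson skewness and excess
  kurtosis (the SPSS estimators, via `e1071` type 2), flagged non-normal
  when |skewness| > 1 or |kurtosis| > 3. The |3| threshold is read as
  *excess* kurtosis (normal = 0), the convention under which that rule is
  usually stated. A constant vector is reported as "moments undefined"
  rather than classified.
* **Spearman ρ** is the Pearson correlation of midranks, computed
  explicitly (not delegated), with `stats::cor` serving as an independent
  oracle in the tests. p-values use the t approximation with n − 2 degrees
  of freedom; an exact permutation p is available for n ≤ 8 (full
  enumeration of n! rank permutations — 8! = 40,320 is the practical limit
  for exhaustive enumeration here, and beyond it the t approximation is
  already accurate). The 95% CI uses the Fisher z transform with the
  Bonett–Wright standard error √((1 + ρ²/2)/(n − 3)), a standard choice for
  rank correlations when the originating analysis does not state its
  interval method.
* **Missing covariates** are deleted pairwise; the per-pair n is reported.

## Numerical and degenerate-input choices

* All schedule times are seconds (double); all engine timestamps are
  integer milliseconds — RT-reporting precision, and logs diff cleanly.
* Configuration errors name the offending field; degenerate designs
  (`gonogo_target_fraction = 1`, zero trials, non-divisible interference
  totals) are rejected at construction.
* The recognition image pool holds 500 abstract identifiers per form;
  requesting more sequences than the pool supports is a generation error.
  Forms A and B index identical pool positions with version-prefixed
  identifiers: structure is shared exactly, identifiers are disjoint by
  construction.
* Serialization uses full-precision JSON; identical objects serialize to
  identical bytes, which the determinism tests assert literally.

## Problem sizes used in verification

The simulation-based checks run at sizes chosen to make their tolerances
statistically comfortable: interval containment over 10,000 generated
trials; debounce neutrality over 100 seeded full-battery sessions; Simon
recovery of a 50 ms effect at 2,000 trials × 100 seeds (tolerance ±10 ms,
where the per-seed standard error is ≈ 3 ms); null-effect calibration over
500 default-size sessions (±3 ms on the grand mean); Spearman equality to
its definitional oracle exhaustively over all 720 permutations at n = 6
plus 1,000 random tied instances at n ≤ 8; and the rank test's type-I error
from 10,000 Monte-Carlo replicates at n = 80.

## Known limitations

* The engine models one timeline per session; pauses, aborts and partial
  task completion appear only as missing outcomes (completion flag false),
  not as first-class states.
* The simulator's independence assumptions (trial-to-trial, tap-to-tap)
  are deliberately simplistic; it cannot exercise sequential effects.
* Correlations of usability with covariates on a *real* cohort require the
  corresponding recorded dataset; the package only verifies the analysis
  machinery on synthetic data with known structure.
* The recognition task uses abstract image identifiers; no statement about
  visual similarity or memorability of real stimuli is made.
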