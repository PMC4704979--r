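---
title: "Adaptive working-memory training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive working-memory training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmtrainr)
library(dplyr)
```

wmtrainr implements the computational core of a self-administered,
at-home working-memory training program of the kind used in cognitive
rehabilitation for people with multiple sclerosis: three exercise
engines, a validity-based adaptive staircase, an intensiveness
scheduler, text-file trial logging with per-patient reports, and the
adherence and questionnaire summaries used to evaluate such a program.
Because no touchscreen patients are available at a desk, a parametric
simulated responder closes the loop and exercises every code path
end-to-end.

## The three exercises

**Visuospatial span (`vs_wm`).** A sequence of `sequence_length`
distinct cells lights up on a `grid_rows x grid_cols` grid (minimum
2x2), one cell every `isi` seconds; the patient reproduces the sequence
by touching cells in order. Scoring is order-sensitive,
position-by-position, with no partial credit: the block percentage is
over all positions. Cells are drawn *without replacement* within a
sequence. The alternative — allowing repeats — would make "touch the
corresponding locations" ambiguous on reproduction, so repeats are
excluded by construction; the direct consequence is
`sequence_length <= grid cells`.

**Operation N-back (`op_nb`).** Each stimulus is a pair of digits drawn
independently and uniformly from `[digit_lo, digit_hi]` (1–9 by
default, so sums span 2–18). The patient answers the *sum* of the pair
shown N stimuli earlier; at N = 0, the current pair.

**Dual N-back (`d_nb`).** Each stimulus is a digit 1–4 shown in one of
4 cells in a row. The answer names both the digit (buttons 1–4) and the
cell (buttons 5–8, 5 = left-most). The two touches form one answer: it
is correct only when both match, and a half-right answer counts as one
incorrect answer, not half of anything.

For both N-back types the first N stimuli are memorize-only, so a block
of `stimulus_count` stimuli has `stimulus_count - N` scored positions,
and the block size is tied to the load by `(N + 1) * 5` — 15 stimuli at
N = 2 (`required_stimulus_count()`).

A missed answer is an explicit state (`NA` in the response encoding)
counted in `n_missed`; timing is simulated throughout (no real-time
loop), with the response window identified with the inter-stimulus
interval, since block time is accounted as `stimuli x isi`.

## The adaptive staircase

After every block, `pct_correct = 100 * n_correct / scored positions`
is compared with the exercise's validity threshold — 100% for the span
task, 80% for operation N-back, 75% for dual N-back in the protocol
preset. The staircase is deliberately asymmetric:

* a **valid** block raises the difficulty level by 1 and a new record is
  spawned;
* an **invalid** block leaves the level unchanged; only the **third
  consecutive** invalid block lowers the level by 1. After the first and
  second invalid block no record is created and the previous one is
  reused.

The streak counter resets after any valid block and after a decrement
(three-in-a-row is read as a consecutive run). The level never moves by
more than one per block, and never drops below the floor (level 1, the
easiest rung): a patient at the bottom who keeps failing stays at the
bottom rather than falling off the ladder.

**The ladder.** Levels map to configurations rate-first: levels
`1..length(rate_steps)` shorten the inter-stimulus interval along
`rate_steps`, ending at the rate threshold (1 s for the span task, 3 s
for the N-back tasks); every level beyond raises the task parameter by
one (sequence length, resp. N) at the threshold rate. The protocol
never states the individual rate steps, only their endpoint, so the
package defaults are a uniform descent chosen once: 2.0 to 1.0 s in
0.25 s steps for the span task and 4.5 to 3.0 s in 0.5 s steps for the
N-back tasks, both configurable per ladder. Starting records are the
same for every patient: 3x3 grid with 3 stimuli, resp. N = 0, at the
slowest rate.

The grid is held fixed during adaptation (only the stimulus count
adapts for the span task in the study protocol; a larger grid can be
supplied as a custom `base_config`). With a fixed 3x3 grid and
without-replacement sampling the span ladder is finite — 5 rate steps
plus 6 length steps, `max_level = 11` — so `advance_state()` takes a
`ceiling`: a valid block at the top keeps the level (and still clears
the streak). The N-back ladders are unbounded.

## The scheduler

`training_program()` holds the intensiveness settings; the
`"takeuchi-8w"` preset is 8 weeks x 5 sessions/week (40 sessions), 30
minutes per session, about 10 minutes per exercise per day, one session
a day. `session_allowed()` enforces the caps block-by-block; weeks are
ISO calendar weeks (the protocol does not anchor its weeks, and ISO
weeks make the weekly cap unambiguous). `run_program()` starts on a
Monday by default so that a 5-per-ISO-week schedule can seat all 40
sessions in 8 weeks.

Adherence is completed sessions over scheduled sessions, in integer
percent rounded half away from zero — the convention that reproduces
printed clinical summaries (33.4/40 → 84%, 15/16 → 94%), where base R's
round-half-to-even would not. `adherence_percent()` accepts fractional
counts so a cohort mean summarizes directly. The analysis-inclusion
threshold is the smallest whole count whose exact completion fraction
reaches the bar (`ceiling(fraction * scheduled / 100)`): 32 of 40 at
80%.

## The simulated responder

`responder_model()` is the smallest psychometric model that can drive
the whole system: each answer is independently correct with probability

```
p(level) = p_high                                    level <= capacity
           max(p_floor, p_high - slope * (level - capacity))   above
```

and missed with probability `miss_rate`, independent of correctness.
`run_block()` generates the stream from the record's config and seed,
draws answers (wrong answers are uniform over the wrong alternatives of
the exercise's response alphabet), and scores them through the real
scorers — never a shortcut on the probabilities.

Defaults are `p_high = 0.95`, `p_floor = 0.05`, `slope = 0.35`,
`miss_rate = 0.02`, fixed once from the exact chain (below) so that the
staircase's modal stationary level sits within one level of the
responder's capacity across capacities 3–8 — the property that makes
capacity recoverable from a long closed-loop run, which is the model's
purpose as a validation instrument. Per-answer independence means no
fatigue, learning, or sequential dependencies: passing tests say the
*engine* behaves correctly under a stationary responder, not that real
patients are stationary.

## Validating the staircase exactly

Because answers are independent, the number correct in a block at a
given level is binomial, so the probability that a block is valid is an
upper-tail binomial probability (`block_valid_probability()`), and the
staircase is exactly a Markov chain on states `(level, invalid_streak)`
with 3 streak states per level. `level_chain_stationary()` builds that
chain (levels truncated to the ladder's range, or where the validity
probability falls below 1e-9 for unbounded ladders) and solves for its
stationary distribution by a linear solve. This closed form is the
independent oracle against which the closed-loop simulation
(`stationary_level_distribution()`, burn-in: first 10% of blocks) is
checked. Because successive levels are strongly autocorrelated, the
Monte-Carlo error used in that comparison is estimated by batch means
(20 batches), not by the naive binomial formula.

```{r chain, eval = FALSE}
m <- responder_model(capacity = 5)
exact <- level_chain_stationary(m, "vs_wm")
sim <- stationary_level_distribution(m, "vs_wm", n_blocks = 4000, seed = 11)
autoplot(exact, empirical = sim)
```

## Persistence

The store mirrors the app's three database sections — patients,
exercises and treatments (records + assignments), settings — as tibbles
with unique primary keys and checked foreign keys; an auto-generated
record refuses assignment to any patient but the one whose performance
spawned it. The raw log is an append-only UTF-8 TSV with one header
line and ISO-8601 timestamps, one line per block, carrying the config
snapshot and stimulus seed for exact replay; numeric fields are written
with enough digits that the reader is an exact inverse of the writer.
`export_bundle()`/`import_bundle()` move a store through a directory of
TSVs with an MD5 manifest, so tampering or truncation is detected on
import. Reports (`generate_report()`) are recomputed from the raw log,
never cached.

## Problem sizes and numerical choices

The test suite replays the staircase against a brute-force oracle over
all 2^n valid/invalid strings for n up to 12, compares a 10,000-block
closed-loop run against the exact stationary distribution, recovers
capacities 3–8 from 2,000-block runs, and checks every scorer against
exhaustive enumeration on blocks of up to 6 stimuli over reduced answer
alphabets — sizes at which exhaustive oracles are still exact yet the
asymptotic behavior is already visible. Threshold comparisons of
percentages use a 1e-9 absolute guard so a count that mathematically
sits on the threshold (e.g. 12 of 15 at 80%) is never lost to floating
point. All randomness flows from explicit integer seeds (one per block,
recorded in the log); a program run is bit-identical under the same
master seed.

## Limitations

* The simulated responder is stationary; learning or fatigue drift
  would need a time-varying capacity, which the staircase would track
  with lag — untested territory by design.
* Session time accounting is simulated (`stimuli x isi`); real response
  latencies would shorten the effective block budget.
* The Likert means of a real cohort are not reproducible from published
  marginals; the evaluation module is validated on synthetic cohorts
  with known parameters instead.
* The store is flat-file relational, adequate for desk-scale cohorts;
  it holds the USER/ADMIN modality as a flag only — there is no GUI,
  rendering, or real-time input anywhere in the package.
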