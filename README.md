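# wmtrainr

Computational core of a self-administered, at-home **working-memory
training program**, of the kind used in cognitive rehabilitation for
people with multiple sclerosis. The package is for rehabilitation
researchers and engineers who need the training engine — not the
touchscreen app around it — as inspectable, testable code: exercise
stimulus generation and scoring, the adaptive difficulty algorithm, the
intensiveness scheduler, trial logging and reports, and the adherence
and questionnaire statistics used to evaluate such an intervention.
Simulated responders stand in for patients, so the whole system runs
closed-loop at a desk.

## What it implements

**Three exercises.** Visuospatial span (reproduce an ordered sequence
of grid cells, drawn without replacement), operation N-back (answer the
sum of the digit pair shown *N* stimuli ago; digits 1–9, sums 2–18),
and dual N-back (name both the digit 1–4 and its cell, deferred by
*N*). N-back blocks present (N + 1) × 5 stimuli, of which the last
`count − N` are scored:

```
pct_correct = 100 · n_correct / (n_correct + n_incorrect + n_missed)
```

**Adaptive working load.** A block is *valid* when `pct_correct`
reaches its exercise threshold (100% span, 80% operation N-back, 75%
dual N-back). The staircase raises the difficulty level by 1 after
every valid block and lowers it by 1 only after **three consecutive**
invalid blocks; otherwise the previous exercise record is reused.
Levels map to configurations rate-first (inter-stimulus interval down
to 1 s, resp. 3 s), then parameter-wise (sequence length, resp. N).
Auto-generated records are bound to their patient.

**Scheduler and outcomes.** The `"takeuchi-8w"` preset schedules 8
weeks × 5 weekly 30-minute sessions (40 total), ~10 minutes per
exercise per day, one session a day. Adherence is completed/scheduled
in integer percent (half-up), and the questionnaire module summarizes
5 yes/no usability items and 4 Likert (1–4) compliance items as
proportions and mean ± SE.

**Validation instrument.** Because simulated answers are independent,
block validity is an exact binomial tail probability and the staircase
is a Markov chain on (level, invalid-streak) states;
`level_chain_stationary()` solves it exactly and the closed-loop
simulation is checked against it.

## Worked example

```r
library(wmtrainr)

model   <- responder_model(capacity = 5)           # simulated patient
history <- run_program(model, program_preset("takeuchi-8w"), seed = 42)
glance(history)
#> # A tibble: 1 × 9
#>   patient_id n_sessions n_blocks scheduled adherence pct_valid max_level_d_nb
#>   <chr>           <int>    <int>     <int>     <dbl>     <dbl>          <int>
#> 1 sim-01             40     6992        40       100      22.9              7
```

All 40 scheduled sessions ran (adherence 100%); the responder executed
6,992 blocks, 22.9% of them valid — the staircase holds a responder
near its capacity, where most blocks fail, climbing one level per valid
block and giving one back after each three-in-a-row failure. The exact
chain says where it settles:

```r
exact <- level_chain_stationary(model, "vs_wm")
exact$levels[exact$levels$prob > 0.01, ]
#>   level  prob
#> 1     5 0.189
#> 2     6 0.595
#> 3     7 0.214
modal_level(exact)
#> [1] 6
```

A capacity-5 responder spends ~60% of its time at level 6 — capacity is
recoverable to within one level from a long run, which is the test the
staircase has to pass. Study-level numbers come from printed counts:

```r
adherence_percent(33.4, program_preset("takeuchi-8w"))   # cohort mean
#> [1] 84
inclusion_threshold_sessions(program_preset("takeuchi-8w"), 80)
#> [1] 32
qs <- read_questionnaire(system.file("extdata",
        "questionnaire_synthetic.tsv", package = "wmtrainr"))
summarize_yesno(qs, c("q1", "q3"))
#>   question n_yes     n percent
#> 1 q1          15    16      94
#> 2 q3          12    16      75
```

(The shipped questionnaire is a *synthetic* cohort whose yes/no margins
match published counts; Likert columns are simulated.)

`autoplot()` works on histories, stationary distributions and
questionnaire summaries; `tidy()`/`glance()` on histories and reports.
A thin command line lives at `inst/cli/wmtrain.R` (`add-patient`,
`assign`, `simulate`, `report`, `export`, `summarize-questionnaire`).

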