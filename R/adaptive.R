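# Validity check, difficulty staircase (+1 per valid block, -1 after three
# consecutive invalid blocks) and the rate-first-then-parameter ladder that
# maps a difficulty level to an exercise configuration.

#' Validity thresholds
#'
#' A block is "valid" when its percent-correct reaches the exercise-specific
#' threshold. The protocol preset demands a perfect visuospatial sequence
#' (100%), 80% on operation N-back and 75% on dual N-back.
#'
#' @param vs_wm,op_nb,d_nb Thresholds in percent, each in (0, 100].
#' @return A `wm_thresholds` list.
#' @examples
#' validity_thresholds()
#' @export
validity_thresholds <- function(vs_wm = 100, op_nb = 80, d_nb = 75) {
  th <- list(vs_wm = vs_wm, op_nb = op_nb, d_nb = d_nb)
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!(is.numeric(v) && length(v) == 1 && v > 0 && v <= 100)) {
      abort_wm(sprintf("threshold `%s` must lie in (0, 100]", nm),
               "wm_config_error")
    }
    th[[nm]] <- as.numeric(v)
  }
  structure(th, class = "wm_thresholds")
}

#' Decide whether a block is valid
#'
#' @param result A `wm_block_result` from [score_stream()].
#' @param thresholds A [validity_thresholds()] object.
#' @return `TRUE` iff `pct_correct` meets the threshold for the result's
#'   exercise type.
#' @examples
#' s <- generate_stream(opnb_config(n_back = 0), seed = 3)
#' r <- score_stream(s, s$items$sum)
#' evaluate_validity(r, validity_thresholds())
#' @export
evaluate_validity <- function(result, thresholds = validity_thresholds()) {
  type <- check_exercise_type(result$exercise_type)
  result$pct_correct >= thresholds[[type]] - .pct_eps
}

#' Adaptive staircase state
#'
#' The state the staircase carries between blocks: the current difficulty
#' level and the number of consecutive invalid blocks seen since the last
#' level change (0–2; a third consecutive invalid block triggers the
#' decrement and resets the streak).
#'
#' @param level Integer level, >= 1.
#' @param invalid_streak Integer 0, 1 or 2.
#' @return A `wm_adaptive_state` list.
#' @export
adaptive_state <- function(level = 1L, invalid_streak = 0L) {
  level <- check_count(level, "level", min = 1L)
  invalid_streak <- check_count(invalid_streak, "invalid_streak", min = 0L)
  if (invalid_streak > 2L) {
    abort_wm("invalid_streak never reaches 3 (the third invalid block decrements)",
             "wm_state_error")
  }
  structure(list(level = level, invalid_streak = invalid_streak),
            class = "wm_adaptive_state")
}

#' Advance the staircase after one block
#'
#' A valid block raises the level by 1 and clears the streak. An invalid
#' block leaves the level alone until it is the third in a row, at which
#' point the level drops by 1 (never below `floor`) and the streak clears.
#' The level thus never moves by more than 1 per block. `ceiling` caps the
#' climb for ladders with a bounded parameter space (a valid block at the
#' ceiling keeps the level and still clears the streak).
#'
#' @param state A [adaptive_state()].
#' @param valid Logical outcome of [evaluate_validity()].
#' @param floor Lowest admissible level (default 1, the easiest rung).
#' @param ceiling Highest admissible level (default unbounded).
#' @return The new `wm_adaptive_state`.
#' @examples
#' advance_state(adaptive_state(3, 0), valid = TRUE)   # -> level 4
#' advance_state(adaptive_state(3, 2), valid = FALSE)  # -> level 2
#' @export
advance_state <- function(state, valid, floor = 1L, ceiling = Inf) {
  stopifnot(inherits(state, "wm_adaptive_state"), is.logical(valid),
            length(valid) == 1, !is.na(valid))
  if (valid) {
    adaptive_state(min(state$level + 1L, ceiling), 0L)
  } else if (state$invalid_streak < 2L) {
    adaptive_state(state$level, state$invalid_streak + 1L)
  } else {
    adaptive_state(max(state$level - 1L, floor), 0L)
  }
}

default_rate_steps <- function(exercise_type) {
  # the rate ladder ends at the protocol's rate threshold:
  # 1 stimulus/s for the span task, 1 per 3 s for the N-back tasks
  if (exercise_type == "vs_wm") seq(2, 1, by = -0.25)
  else seq(4.5, 3, by = -0.5)
}

default_base_config <- function(exercise_type, rate_steps) {
  switch(exercise_type,
         vs_wm = vswm_config(3, 3, sequence_length = 3, isi = rate_steps[[1]]),
         op_nb = opnb_config(n_back = 0, isi = rate_steps[[1]]),
         d_nb  = dnb_config(n_back = 0, isi = rate_steps[[1]]))
}

#' Difficulty ladder
#'
#' Maps integer difficulty levels to exercise configurations. Levels
#' `1..length(rate_steps)` shorten the inter-stimulus interval along
#' `rate_steps`, holding the task parameter at its base value; each level
#' beyond the last rate step raises the task-specific parameter by 1
#' (sequence length for the span task; N — and with it the stimulus count
#' `(N+1)*5` — for the N-back tasks) at the threshold rate. Consecutive
#' levels therefore differ in exactly one parameter.
#'
#' For the span task with a fixed grid the ladder is finite: sequences are
#' drawn without replacement, so the sequence length cannot exceed the
#' number of grid cells and `max_level` defaults to
#' `length(rate_steps) + cells - base length` (11 for the 3x3 preset).
#'
#' @param exercise_type `"vs_wm"`, `"op_nb"` or `"d_nb"`.
#' @param rate_steps Strictly decreasing vector of inter-stimulus intervals
#'   in seconds, ending at the rate threshold. Defaults: 2.0 to 1.0 s in
#'   0.25 s steps (span), 4.5 to 3.0 s in 0.5 s steps (N-back).
#' @param base_config Configuration at level 1 (slowest rate, base
#'   parameter). Defaults: 3x3 grid with 3 stimuli; N = 0.
#' @param max_level Highest level the ladder defines (`Inf` when the
#'   parameter is unbounded).
#' @return A `wm_ladder` list.
#' @examples
#' lad <- difficulty_ladder("op_nb")
#' config_at_level(lad, 5) # N = 1 at the 3 s threshold rate
#' @export
difficulty_ladder <- function(exercise_type,
                              rate_steps = default_rate_steps(exercise_type),
                              base_config = default_base_config(exercise_type, rate_steps),
                              max_level = NULL) {
  check_exercise_type(exercise_type)
  rate_steps <- as.numeric(rate_steps)
  if (length(rate_steps) < 1 || any(rate_steps <= 0) ||
      any(diff(rate_steps) >= 0)) {
    abort_wm("rate_steps must be a strictly decreasing vector of positive ISIs",
             "wm_config_error")
  }
  if (exercise_type_of(base_config) != exercise_type) {
    abort_wm("base_config does not match exercise_type", "wm_config_error")
  }
  if (is.null(max_level)) {
    max_level <- if (exercise_type == "vs_wm") {
      length(rate_steps) +
        (base_config$grid_rows * base_config$grid_cols -
           base_config$sequence_length)
    } else {
      Inf
    }
  }
  structure(
    list(exercise_type = exercise_type, rate_steps = rate_steps,
         base_config = base_config, max_level = max_level),
    class = "wm_ladder"
  )
}

#' Protocol ladders for the three exercises
#'
#' @return Named list of [difficulty_ladder()] objects, one per exercise.
#' @export
default_ladders <- function() {
  list(vs_wm = difficulty_ladder("vs_wm"),
       op_nb = difficulty_ladder("op_nb"),
       d_nb  = difficulty_ladder("d_nb"))
}

#' Configuration at a ladder level
#'
#' @param ladder A [difficulty_ladder()].
#' @param level Integer level >= 1 (and at most `ladder$max_level`).
#' @return The exercise config at that level.
#' @examples
#' config_at_level(difficulty_ladder("vs_wm"), 6) # isi 1.0, length 4
#' @export
config_at_level <- function(ladder, level) {
  stopifnot(inherits(ladder, "wm_ladder"))
  level <- check_count(level, "level", min = 1L)
  if (level > ladder$max_level) {
    abort_wm(sprintf("level %d exceeds the ladder's top level (%s)",
                     level, format(ladder$max_level)),
             "wm_domain_error")
  }
  r <- length(ladder$rate_steps)
  base <- ladder$base_config
  if (level <= r) {
    base$isi <- ladder$rate_steps[[level]]
    return(base)
  }
  extra <- level - r
  base$isi <- ladder$rate_steps[[r]]
  if (ladder$exercise_type == "vs_wm") {
    vswm_config(base$grid_rows, base$grid_cols,
                sequence_length = base$sequence_length + extra,
                isi = base$isi)
  } else if (ladder$exercise_type == "op_nb") {
    opnb_config(n_back = base$n_back + extra, digit_lo = base$digit_lo,
                digit_hi = base$digit_hi, isi = base$isi)
  } else {
    dnb_config(n_back = base$n_back + extra, isi = base$isi)
  }
}

#' Exercise records
#'
#' A record is one stored parameter configuration of one exercise type, the
#' unit the staircase assigns to a patient. Records spawned by the adaptive
#' algorithm are flagged `auto_generated` and are bound to the patient whose
#' performance produced them: the datastore refuses to assign them to
#' anyone else.
#'
#' @param record_id Unique identifier.
#' @param patient_id Patient the record belongs to, or `NA` for a shared
#'   starting record not yet bound.
#' @param config Exercise configuration at the record's level.
#' @param level Ladder level of the config.
#' @param auto_generated Was the record spawned by the staircase?
#' @param parent_record_id Record executed just before this one was spawned.
#' @return A `wm_record` list.
#' @export
exercise_record <- function(record_id, patient_id, config, level,
                            auto_generated = FALSE,
                            parent_record_id = NA_character_) {
  stopifnot(inherits(config, "wm_config"))
  level <- check_count(level, "level", min = 1L)
  if (isTRUE(auto_generated) && is.na(patient_id)) {
    abort_wm("auto-generated records must be bound to a patient",
             "wm_state_error")
  }
  structure(
    list(record_id = as.character(record_id),
         patient_id = as.character(patient_id),
         exercise_type = exercise_type_of(config),
         config = config, level = level,
         auto_generated = isTRUE(auto_generated),
         parent_record_id = as.character(parent_record_id)),
    class = "wm_record"
  )
}

#' @rdname exercise_record
#' @param ladder Ladder whose level-1 config seeds the record.
#' @export
starting_record <- function(record_id, patient_id, ladder) {
  exercise_record(record_id, patient_id, config_at_level(ladder, 1L),
                  level = 1L, auto_generated = FALSE)
}

record_counter <- new.env(parent = emptyenv())
record_counter$n <- 0L

next_record_id <- function() {
  record_counter$n <- record_counter$n + 1L
  sprintf("rec%06d", record_counter$n)
}

#' Spawn the next exercise record
#'
#' After a block, the staircase either moved the level — in which case a
#' fresh auto-generated record at the new level is created, bound to the
#' same patient and linked to its parent — or left it unchanged, in which
#' case no record is created and the previous one is reused.
#'
#' @param previous The record just executed (must carry a `patient_id`).
#' @param new_state State returned by [advance_state()].
#' @param ladder The exercise's [difficulty_ladder()].
#' @param record_id Identifier for the spawned record (auto-assigned when
#'   `NULL`).
#' @return A new `wm_record`, or `NULL` when the level is unchanged (the
#'   previous record is adopted for the next block).
#' @export
spawn_record <- function(previous, new_state, ladder, record_id = NULL) {
  stopifnot(inherits(previous, "wm_record"),
            inherits(new_state, "wm_adaptive_state"))
  if (is.na(previous$patient_id)) {
    abort_wm("cannot spawn from a record with no assigned patient",
             "wm_state_error")
  }
  if (new_state$level == previous$level) {
    return(NULL)
  }
  exercise_record(record_id %||% next_record_id(),
                  patient_id = previous$patient_id,
                  config = config_at_level(ladder, new_state$level),
                  level = new_state$level,
                  auto_generated = TRUE,
                  parent_record_id = previous$record_id)
}
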