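# Parametric simulated responders: per-answer psychometric model, closed-loop
# block execution through the real generators and scorers, full-program
# simulation under the scheduler, and the exact (level, streak) Markov chain
# used to validate the staircase.

#' Simulated responder
#'
#' A simulated patient answering exercise stimuli. Below or at its capacity
#' level every answer is correct with probability `p_high`; each level above
#' capacity degrades the probability linearly by `slope`, floored at
#' `p_floor`. Independently of correctness, each answer is missed with
#' probability `miss_rate`. Answers are independent across positions and
#' blocks — no fatigue, learning or sequential effects.
#'
#' The defaults give a responder whose closed-loop modal difficulty level
#' tracks its capacity to within one level, which is what makes capacity
#' recoverable from a long run.
#'
#' @param capacity Capacity level, a scalar or a vector named `vs_wm`,
#'   `op_nb`, `d_nb`.
#' @param p_high Per-answer correctness probability at or below capacity.
#' @param p_floor Lower bound on the correctness probability.
#' @param slope Per-level drop in correctness above capacity (>= 0).
#' @param miss_rate Probability an answer is missed, in \[0, 1).
#' @return A `wm_responder` list.
#' @examples
#' responder_model(capacity = 5)
#' @export
responder_model <- function(capacity = 5, p_high = 0.95, p_floor = 0.05,
                            slope = 0.35, miss_rate = 0.02) {
  if (length(capacity) == 1 && is.null(names(capacity))) {
    capacity <- stats::setNames(rep(capacity, 3), exercise_types())
  }
  stopifnot(all(exercise_types() %in% names(capacity)))
  capacity <- vapply(capacity[exercise_types()], check_count, 1L,
                     name = "capacity", min = 1L)
  if (!(p_floor >= 0 && p_floor <= p_high && p_high <= 1)) {
    abort_wm("need 0 <= p_floor <= p_high <= 1", "wm_config_error")
  }
  if (slope < 0) abort_wm("slope must be >= 0", "wm_config_error")
  if (miss_rate < 0 || miss_rate >= 1) {
    abort_wm("miss_rate must lie in [0, 1)", "wm_config_error")
  }
  structure(list(capacity = capacity, p_high = p_high, p_floor = p_floor,
                 slope = slope, miss_rate = miss_rate),
            class = "wm_responder")
}

#' Per-answer correctness probability at a level
#'
#' `p_high` at or below capacity, then `max(p_floor, p_high - slope *
#' (level - capacity))`.
#'
#' @param model A [responder_model()].
#' @param level Difficulty level (>= 1).
#' @param exercise_type Which capacity to use.
#' @return Probability in \[0, 1\].
#' @examples
#' m <- responder_model(capacity = 5, p_high = 0.95, slope = 0.3, p_floor = 0.05)
#' answer_probability(m, 8) # clipped at the floor
#' @export
answer_probability <- function(model, level, exercise_type = "vs_wm") {
  stopifnot(inherits(model, "wm_responder"))
  check_exercise_type(exercise_type)
  level <- check_count(level, "level", min = 1L)
  cap <- model$capacity[[exercise_type]]
  if (level <= cap) model$p_high
  else max(model$p_floor, model$p_high - model$slope * (level - cap))
}

# draw the responses of one block: per scored position, missed with
# miss_rate, else the true answer with probability p, else a uniformly
# drawn wrong answer from the exercise's response alphabet
simulate_responses <- function(model, stream, p, seed) {
  cfg <- stream$config
  n <- n_scored(cfg)
  withr::with_seed(seed, {
    missed <- runif(n) < model$miss_rate
    correct <- runif(n) < p
    if (stream$exercise_type == "vs_wm") {
      truth <- stream$items$cell
      resp <- truth
      wrong <- which(!correct)
      n_cells <- cfg$grid_rows * cfg$grid_cols
      for (i in wrong) {
        resp[i] <- sample(setdiff(seq_len(n_cells), truth[i]), 1)
      }
      resp[missed] <- NA_integer_
      resp
    } else if (stream$exercise_type == "op_nb") {
      truth <- stream$items$sum[seq_len(n)]
      resp <- truth
      lo <- 2L * cfg$digit_lo
      hi <- 2L * cfg$digit_hi
      for (i in which(!correct)) {
        alts <- setdiff(lo:hi, truth[i])
        resp[i] <- if (length(alts)) sample(alts, 1) else truth[i] + 1L
      }
      resp[missed] <- NA_integer_
      resp
    } else {
      td <- stream$items$digit[seq_len(n)]
      tc <- stream$items$cell[seq_len(n)]
      db <- td
      cb <- tc + 4L
      for (i in which(!correct)) {
        pair <- sample.int(16L, 1)
        d <- (pair - 1L) %% 4L + 1L
        cc <- (pair - 1L) %/% 4L + 1L
        if (d == td[i] && cc == tc[i]) d <- d %% 4L + 1L
        db[i] <- d
        cb[i] <- cc + 4L
      }
      db[missed] <- NA_integer_
      cb[missed] <- NA_integer_
      data.frame(digit_button = db, cell_button = cb)
    }
  })
}

#' Execute one block with a simulated responder
#'
#' Generates the stimulus stream from the record's configuration and seed,
#' draws the responder's answers, and scores them through the exercise
#' scorers (the result is never shortcut-computed from the probabilities).
#'
#' @param model A [responder_model()].
#' @param record The `wm_record` to execute.
#' @param seed Block seed (stimulus stream; the response draw uses a seed
#'   derived from it).
#' @param timestamp Timestamp stored on the result.
#' @return A `wm_block_result`.
#' @examples
#' rec <- starting_record("r1", "p1", difficulty_ladder("vs_wm"))
#' run_block(responder_model(capacity = 5), rec, seed = 42)
#' @export
run_block <- function(model, record, seed, timestamp = Sys.time()) {
  stopifnot(inherits(model, "wm_responder"), inherits(record, "wm_record"))
  stream <- generate_stream(record$config, seed)
  p <- answer_probability(model, record$level, record$exercise_type)
  responses <- simulate_responses(model, stream, p, derive_seed(seed, 7L))
  score_stream(stream, responses, level = record$level, timestamp = timestamp)
}

#' Run a full training program closed-loop
#'
#' Simulates the whole intervention: sessions are placed on consecutive
#' eligible days under [session_allowed()]; within each session the three
#' exercises run in turn, each accumulating blocks until its daily time
#' budget (simulated time: stimuli x ISI) is exhausted; every block is
#' scored, checked for validity, fed to the staircase, and — when the level
#' moves — a new patient-bound record is spawned. The whole history is a
#' deterministic function of `seed`.
#'
#' @param model A [responder_model()].
#' @param program A [training_program()].
#' @param ladders Named list of ladders (see [default_ladders()]).
#' @param thresholds A [validity_thresholds()].
#' @param seed Integer master seed.
#' @param start_date First training day; the default is a Monday so that a
#'   5-per-ISO-week schedule can place all sessions.
#' @param patient_id Identifier used in records and logs.
#' @param store Optional [wm_store()]: when given, the patient, every
#'   record and every raw-log line are persisted in it.
#' @return A `wm_history`: list with `patient_id`, `seed`, `program`,
#'   `sessions` (one row per session), `blocks` (one row per executed
#'   block) and `records` (every record used or spawned).
#' @examples
#' h <- run_program(responder_model(capacity = 4), seed = 1)
#' nrow(h$sessions) # 40
#' @export
run_program <- function(model, program = program_preset(),
                        ladders = default_ladders(),
                        thresholds = validity_thresholds(),
                        seed = 1L,
                        start_date = as.Date("2012-01-02"),
                        patient_id = "sim-01",
                        store = NULL) {
  stopifnot(inherits(model, "wm_responder"), inherits(program, "wm_program"))
  seed <- check_count(seed, "seed", min = 0L)
  start_date <- as.Date(start_date)
  scheduled <- scheduled_session_count(program)
  if (!is.null(store)) upsert_patient(store, patient_id)

  states <- lapply(exercise_types(), function(t) adaptive_state())
  names(states) <- exercise_types()
  records <- list()
  current <- list()
  rec_n <- 0L
  for (t in exercise_types()) {
    rec_n <- rec_n + 1L
    rec <- starting_record(sprintf("%s-%04d", patient_id, rec_n), patient_id,
                           ladders[[t]])
    current[[t]] <- rec
    records[[length(records) + 1L]] <- rec
    if (!is.null(store)) {
      upsert_record(store, rec)
      upsert_assignment(store, sprintf("asg-%s-%s", patient_id, t),
                        patient_id, rec$record_id, ordinal = 1L,
                        adaptive_enabled = TRUE)
    }
  }

  blocks <- list()
  sessions <- list()
  session_days <- as.Date(character())
  day <- start_date
  block_n <- 0L
  while (length(sessions) < scheduled) {
    if (!session_allowed(session_days, day, program)) {
      day <- day + 1L
      if (day > start_date + 7L * program$duration_weeks) break
      next
    }
    session_no <- length(sessions) + 1L
    t0 <- as.POSIXct(paste0(format(day), " 09:00:00"), tz = "UTC")
    session_seconds <- 0
    session_blocks <- 0L
    for (t in exercise_types()) {
      budget <- program$per_exercise_daily_minutes[[t]] * 60
      used <- 0
      n_in_exercise <- 0L
      repeat {
        cfg <- current[[t]]$config
        block_seconds <- n_stimuli(cfg) * cfg$isi
        if (n_in_exercise > 0L && used + block_seconds > budget) break
        block_n <- block_n + 1L
        block_seed <- derive_seed(seed, block_n)
        res <- run_block(model, current[[t]], block_seed,
                         timestamp = t0 + session_seconds + used)
        valid <- evaluate_validity(res, thresholds)
        if (!is.null(store)) {
          append_raw_log(res, current[[t]], store$log_path,
                         seed = block_seed, valid = valid)
        }
        blocks[[block_n]] <- c(
          list(session = session_no, date = day),
          as.list(res[, c("exercise_type", "level", "n_correct",
                          "n_incorrect", "n_missed", "pct_correct",
                          "timestamp")]),
          list(valid = valid, seed = block_seed,
               record_id = current[[t]]$record_id))
        new_state <- advance_state(states[[t]], valid,
                                   ceiling = ladders[[t]]$max_level)
        rec_n <- rec_n + 1L
        nxt <- spawn_record(current[[t]], new_state, ladders[[t]],
                            record_id = sprintf("%s-%04d", patient_id, rec_n))
        if (is.null(nxt)) {
          rec_n <- rec_n - 1L
        } else {
          current[[t]] <- nxt
          records[[length(records) + 1L]] <- nxt
          if (!is.null(store)) upsert_record(store, nxt)
        }
        states[[t]] <- new_state
        used <- used + block_seconds
        n_in_exercise <- n_in_exercise + 1L
      }
      session_seconds <- session_seconds + used
      session_blocks <- session_blocks + n_in_exercise
    }
    sessions[[session_no]] <- list(session = session_no, date = day,
                                   n_blocks = session_blocks,
                                   total_minutes = session_seconds / 60)
    session_days <- c(session_days, day)
    day <- day + 1L
  }

  history <- structure(
    list(patient_id = patient_id, seed = seed, program = program,
         sessions = dplyr::bind_rows(sessions),
         blocks = dplyr::bind_rows(blocks),
         records = dplyr::bind_rows(lapply(records, function(r) {
           tibble::tibble(record_id = r$record_id, patient_id = r$patient_id,
                          exercise_type = r$exercise_type, level = r$level,
                          auto_generated = r$auto_generated,
                          parent_record_id = r$parent_record_id,
                          config = serialize_config(r$config))
         }))),
    class = "wm_history")
  history
}

#' @export
print.wm_history <- function(x, ...) {
  cat(sprintf("<wm_history: patient %s, %d sessions, %d blocks, seed %d>\n",
              x$patient_id, nrow(x$sessions), nrow(x$blocks), x$seed))
  invisible(x)
}

#' Empirical stationary level distribution
#'
#' Runs one exercise closed-loop for `n_blocks` blocks (no scheduler: the
#' staircase alone drives difficulty) and tabulates the level occupied at
#' each block after discarding the burn-in. This is the simulation side of
#' the staircase validation; [level_chain_stationary()] is the exact side.
#'
#' @param model A [responder_model()].
#' @param exercise_type Exercise to run.
#' @param n_blocks Number of blocks (>= 1).
#' @param seed Integer seed.
#' @param ladder Ladder for the exercise.
#' @param thresholds A [validity_thresholds()].
#' @param burn_in Fraction of initial blocks discarded (default 10%).
#' @return Tibble with `level`, `n`, `freq`; the full post-burn-in level
#'   trajectory is in attribute `trajectory`.
#' @export
stationary_level_distribution <- function(model, exercise_type = "vs_wm",
                                          n_blocks = 2000, seed = 1L,
                                          ladder = difficulty_ladder(exercise_type),
                                          thresholds = validity_thresholds(),
                                          burn_in = 0.1) {
  check_exercise_type(exercise_type)
  n_blocks <- check_count(n_blocks, "n_blocks", min = 1L)
  state <- adaptive_state()
  configs <- list()
  levels <- integer(n_blocks)
  rec <- starting_record("sim", "sim", ladder)
  for (b in seq_len(n_blocks)) {
    levels[[b]] <- state$level
    res <- run_block(model, rec, derive_seed(seed, b))
    valid <- evaluate_validity(res, thresholds)
    state <- advance_state(state, valid, ceiling = ladder$max_level)
    if (state$level != rec$level) {
      rec <- exercise_record("sim", "sim", config_at_level(ladder, state$level),
                             level = state$level, auto_generated = TRUE,
                             parent_record_id = "sim")
    }
  }
  keep <- levels[(floor(burn_in * n_blocks) + 1L):n_blocks]
  tab <- table(keep)
  out <- tibble::tibble(level = as.integer(names(tab)),
                        n = as.integer(tab),
                        freq = as.integer(tab) / length(keep))
  attr(out, "trajectory") <- keep
  out
}

#' Probability one block is valid
#'
#' Exact probability that a block at `level` reaches its validity
#' threshold: each scored position is correct with probability
#' `(1 - miss_rate) * answer_probability(level)`, so the number correct is
#' binomial and validity is an upper-tail binomial probability.
#'
#' @inheritParams stationary_level_distribution
#' @param level Difficulty level.
#' @return Probability in \[0, 1\].
#' @export
block_valid_probability <- function(model, level, exercise_type = "vs_wm",
                                    ladder = difficulty_ladder(exercise_type),
                                    thresholds = validity_thresholds()) {
  cfg <- config_at_level(ladder, level)
  n <- n_scored(cfg)
  q <- (1 - model$miss_rate) * answer_probability(model, level, exercise_type)
  k <- ceiling(thresholds[[exercise_type]] * n / 100 - .pct_eps)
  pbinom(k - 1, n, q, lower.tail = FALSE)
}

#' Exact stationary distribution of the staircase
#'
#' Builds the Markov chain on states `(level, invalid_streak)` implied by
#' the staircase rules — up 1 with the block-validity probability, streak
#' accumulation otherwise, down 1 on the third consecutive invalid block —
#' with levels truncated to `[floor, max_level]`, and solves for its
#' stationary distribution. Serves as the independent oracle for the
#' closed-loop simulation.
#'
#' @inheritParams block_valid_probability
#' @param floor Lowest level.
#' @param max_level Highest level of the chain; defaults to the ladder's
#'   top level or, for unbounded ladders, the lowest level at which the
#'   block-validity probability falls below `1e-9`.
#' @return List of class `wm_level_chain`: `states` tibble (`level`,
#'   `streak`, `prob`), `levels` tibble (marginal `level`, `prob`), and
#'   `p_valid` by level.
#' @export
level_chain_stationary <- function(model, exercise_type = "vs_wm",
                                   ladder = difficulty_ladder(exercise_type),
                                   thresholds = validity_thresholds(),
                                   floor = 1L, max_level = NULL) {
  if (is.null(max_level)) {
    if (is.finite(ladder$max_level)) {
      max_level <- ladder$max_level
    } else {
      max_level <- floor
      repeat {
        if (block_valid_probability(model, max_level, exercise_type, ladder,
                                    thresholds) < 1e-9 ||
            max_level > 500L) break
        max_level <- max_level + 1L
      }
    }
  }
  lv <- floor:max_level
  pv <- vapply(lv, function(l) {
    block_valid_probability(model, l, exercise_type, ladder, thresholds)
  }, 0)
  if (pv[[length(pv)]] > 1e-6 && is.finite(ladder$max_level) == FALSE) {
    rlang::warn("chain truncated while the validity probability is still non-negligible")
  }
  states <- expand.grid(streak = 0:2, level = lv)[, c("level", "streak")]
  S <- nrow(states)
  idx <- function(l, s) (match(l, lv) - 1L) * 3L + s + 1L
  P <- matrix(0, S, S)
  for (i in seq_len(S)) {
    l <- states$level[[i]]
    s <- states$streak[[i]]
    p <- pv[[match(l, lv)]]
    up <- min(l + 1L, max_level)
    P[i, idx(up, 0L)] <- P[i, idx(up, 0L)] + p
    if (s < 2L) {
      P[i, idx(l, s + 1L)] <- P[i, idx(l, s + 1L)] + (1 - p)
    } else {
      dn <- max(l - 1L, floor)
      P[i, idx(dn, 0L)] <- P[i, idx(dn, 0L)] + (1 - p)
    }
  }
  A <- rbind(t(diag(S) - P), rep(1, S))
  pi_vec <- qr.solve(A, c(rep(0, S), 1))
  pi_vec <- pmax(pi_vec, 0)
  pi_vec <- pi_vec / sum(pi_vec)
  states$prob <- pi_vec
  levels <- states |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
  structure(list(states = tibble::as_tibble(states),
                 levels = levels,
                 p_valid = tibble::tibble(level = lv, p_valid = pv)),
            class = "wm_level_chain")
}

#' @export
print.wm_level_chain <- function(x, ...) {
  cat(sprintf("<wm_level_chain: levels %d..%d, modal level %d>\n",
              min(x$levels$level), max(x$levels$level),
              x$levels$level[[which.max(x$levels$prob)]]))
  invisible(x)
}

#' Modal level of a stationary distribution
#'
#' @param x A `wm_level_chain` or the tibble returned by
#'   [stationary_level_distribution()].
#' @return The level with the highest stationary mass / empirical
#'   frequency.
#' @export
modal_level <- function(x) {
  if (inherits(x, "wm_level_chain")) {
    x$levels$level[[which.max(x$levels$prob)]]
  } else {
    x$level[[which.max(x$freq)]]
  }
}
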