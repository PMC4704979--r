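# Training intensiveness: program duration, weekly frequency, session and
# per-exercise time budgets, session eligibility, adherence accounting.

#' Training program (intensiveness settings)
#'
#' Holds the quantities that determine how much training a patient receives:
#' program duration in weeks, sessions per week, the daily cap, session
#' length and the per-exercise daily time budget. The protocol preset
#' (`program_preset("takeuchi-8w")`, also the default here) prescribes 8
#' weeks of 5 weekly 30-minute sessions — 40 sessions in total — with about
#' 10 minutes per exercise type and at most one session a day.
#'
#' @param duration_weeks Program length in weeks (>= 1).
#' @param sessions_per_week Sessions scheduled per ISO week.
#' @param max_training_days_per_week Days per ISO week on which training is
#'   allowed (`sessions_per_week <= max_training_days_per_week <= 7`).
#' @param session_minutes Length of one session, minutes.
#' @param per_exercise_daily_minutes Named numeric vector (`vs_wm`, `op_nb`,
#'   `d_nb`): daily time budget per exercise type, minutes.
#' @param max_sessions_per_day Daily session cap.
#' @return A `wm_program` list.
#' @examples
#' scheduled_session_count(training_program()) # 40
#' @export
training_program <- function(duration_weeks = 8,
                             sessions_per_week = 5,
                             max_training_days_per_week = sessions_per_week,
                             session_minutes = 30,
                             per_exercise_daily_minutes = c(vs_wm = 10, op_nb = 10, d_nb = 10),
                             max_sessions_per_day = 1) {
  duration_weeks <- check_count(duration_weeks, "duration_weeks", min = 1L)
  sessions_per_week <- check_count(sessions_per_week, "sessions_per_week", min = 1L)
  max_training_days_per_week <- check_count(max_training_days_per_week,
                                            "max_training_days_per_week", min = 1L)
  max_sessions_per_day <- check_count(max_sessions_per_day, "max_sessions_per_day", min = 1L)
  if (sessions_per_week > max_training_days_per_week * max_sessions_per_day ||
      max_training_days_per_week > 7L) {
    abort_wm("need sessions_per_week <= max_training_days_per_week * max_sessions_per_day and at most 7 training days a week",
             "wm_config_error")
  }
  session_minutes <- check_positive(session_minutes, "session_minutes")
  stopifnot(all(exercise_types() %in% names(per_exercise_daily_minutes)))
  structure(
    list(duration_weeks = duration_weeks,
         sessions_per_week = sessions_per_week,
         max_training_days_per_week = max_training_days_per_week,
         session_minutes = session_minutes,
         per_exercise_daily_minutes = vapply(per_exercise_daily_minutes[exercise_types()],
                                             as.numeric, 0),
         max_sessions_per_day = max_sessions_per_day),
    class = "wm_program"
  )
}

#' @rdname training_program
#' @param name Preset name; `"takeuchi-8w"` is the 8-week, 5-sessions-a-week
#'   home-training schedule.
#' @export
program_preset <- function(name = "takeuchi-8w") {
  switch(name,
         "takeuchi-8w" = training_program(),
         abort_wm(sprintf("unknown program preset '%s'", name),
                  "wm_lookup_error"))
}

#' Total sessions a program schedules
#'
#' @param program A [training_program()].
#' @return `duration_weeks * sessions_per_week`.
#' @examples
#' scheduled_session_count(training_program(8, 5)) # 40
#' @export
scheduled_session_count <- function(program) {
  stopifnot(inherits(program, "wm_program"))
  program$duration_weeks * program$sessions_per_week
}

iso_week <- function(date) format(as.Date(date), "%G-W%V")

session_dates <- function(history) {
  if (inherits(history, "wm_history")) history <- history$sessions
  if (is.null(history) || (is.data.frame(history) && nrow(history) == 0)) {
    return(as.Date(character()))
  }
  if (is.data.frame(history)) as.Date(history$date) else as.Date(history)
}

#' May a session start on this date?
#'
#' Enforces the intensiveness limits block by block: at most
#' `max_sessions_per_day` sessions per calendar day, at most
#' `sessions_per_week` sessions (on at most `max_training_days_per_week`
#' distinct days) per ISO week, and nothing once the program's weeks have
#' elapsed since the first session.
#'
#' @param history Past sessions: a data frame with a `date` column, a
#'   `Date` vector, or a `wm_history`.
#' @param date Proposed session date.
#' @param program A [training_program()].
#' @return `TRUE` iff a session on `date` respects every limit.
#' @examples
#' p <- training_program()
#' session_allowed(as.Date(character()), as.Date("2012-01-02"), p)
#' @export
session_allowed <- function(history, date, program) {
  stopifnot(inherits(program, "wm_program"))
  date <- as.Date(date)
  past <- session_dates(history)
  if (any(past > date)) {
    abort_wm("history contains sessions after `date`", "wm_input_error")
  }
  if (sum(past == date) >= program$max_sessions_per_day) return(FALSE)
  wk <- past[iso_week(past) == iso_week(date)]
  if (length(wk) >= program$sessions_per_week) return(FALSE)
  if (length(unique(wk)) >= program$max_training_days_per_week &&
      !(date %in% wk)) return(FALSE)
  start <- min(c(past, date))
  if (date >= start + 7L * program$duration_weeks) return(FALSE)
  TRUE
}

#' Adherence to the scheduled program
#'
#' Completed sessions as a percentage of scheduled sessions, rounded half
#' up to an integer percent. Fractional `completed` counts are accepted so
#' cohort means summarize directly (a cohort averaging 33.4 of 40 sessions
#' adheres at 84%).
#'
#' @param completed Completed session count (may be fractional; vectorized).
#' @param program A [training_program()].
#' @return Integer percent(s).
#' @examples
#' adherence_percent(33.4, training_program()) # 84
#' @export
adherence_percent <- function(completed, program) {
  scheduled <- scheduled_session_count(program)
  if (scheduled <= 0) abort_wm("no sessions scheduled", "wm_domain_error")
  if (any(completed < 0)) abort_wm("completed must be >= 0", "wm_domain_error")
  round_half_up(100 * completed / scheduled)
}

#' Sessions needed to reach an inclusion fraction
#'
#' Smallest whole session count whose completion fraction reaches
#' `fraction` percent of the scheduled sessions — e.g. 32 of 40 at the 80%
#' analysis-inclusion cut-off.
#'
#' @param program A [training_program()].
#' @param fraction Required completion percentage in (0, 100].
#' @return Integer session count.
#' @examples
#' inclusion_threshold_sessions(training_program(), 80) # 32
#' @export
inclusion_threshold_sessions <- function(program, fraction) {
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction <= 100)) {
    abort_wm("fraction must lie in (0, 100]", "wm_domain_error")
  }
  scheduled <- scheduled_session_count(program)
  as.integer(ceiling(fraction * scheduled / 100 - .pct_eps))
}
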