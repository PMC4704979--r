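# broom-style accessors for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated training history
#'
#' `tidy()` returns the per-block table (one row per executed block);
#' `glance()` returns a one-row program summary with the session count,
#' adherence against the program schedule, and the maximum level reached
#' per exercise.
#'
#' @param x A `wm_history` from [run_program()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wm_history
#' @export
tidy.wm_history <- function(x, ...) x$blocks

#' @rdname tidy.wm_history
#' @method glance wm_history
#' @export
glance.wm_history <- function(x, ...) {
  max_lv <- x$blocks |>
    dplyr::group_by(.data$exercise_type) |>
    dplyr::summarise(max_level = max(.data$level), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "exercise_type",
                       values_from = "max_level",
                       names_prefix = "max_level_")
  dplyr::bind_cols(
    tibble::tibble(patient_id = x$patient_id,
                   n_sessions = nrow(x$sessions),
                   n_blocks = nrow(x$blocks),
                   scheduled = scheduled_session_count(x$program),
                   adherence = adherence_percent(nrow(x$sessions), x$program),
                   pct_valid = 100 * mean(x$blocks$valid)),
    max_lv)
}

#' Tidy a patient report
#'
#' `tidy()` returns the per-block table, `glance()` the per-exercise
#' maximum levels in one row.
#'
#' @param x A `wm_report` from [generate_report()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wm_report
#' @export
tidy.wm_report <- function(x, ...) x$blocks

#' @rdname tidy.wm_report
#' @method glance wm_report
#' @export
glance.wm_report <- function(x, ...) {
  wide <- if (nrow(x$max_levels) > 0) {
    tidyr::pivot_wider(x$max_levels, names_from = "exercise_type",
                       values_from = "max_level",
                       names_prefix = "max_level_")
  } else {
    tibble::tibble()
  }
  dplyr::bind_cols(tibble::tibble(patient_id = x$patient_id,
                                  n_blocks = nrow(x$blocks)), wide)
}

#' Tidy an exact staircase chain
#'
#' @param x A `wm_level_chain` from [level_chain_stationary()].
#' @param ... Unused.
#' @return The `(level, streak, prob)` state table.
#' @method tidy wm_level_chain
#' @export
tidy.wm_level_chain <- function(x, ...) x$states
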