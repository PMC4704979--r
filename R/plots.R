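# ggplot2 views of histories, stationary distributions and questionnaire
# summaries.

#' @import ggplot2
NULL

#' Plot a training history
#'
#' Difficulty-level trajectory over consecutive blocks, one panel per
#' exercise type.
#'
#' @param object A `wm_history` from [run_program()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wm_history
#' @export
autoplot.wm_history <- function(object, ...) {
  df <- object$blocks |>
    dplyr::group_by(.data$exercise_type) |>
    dplyr::mutate(block = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot(df, aes(x = .data$block, y = .data$level)) +
    geom_step(colour = "steelblue") +
    facet_wrap(~.data$exercise_type, scales = "free_x") +
    labs(x = "block", y = "difficulty level",
         title = sprintf("Adaptive level trajectory (patient %s)",
                         object$patient_id)) +
    theme_minimal()
}

#' Plot a stationary level distribution
#'
#' Exact stationary level probabilities of the staircase chain; overlay an
#' empirical distribution from [stationary_level_distribution()] to compare
#' simulation against the oracle.
#'
#' @param object A `wm_level_chain`.
#' @param empirical Optional tibble from [stationary_level_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wm_level_chain
#' @export
autoplot.wm_level_chain <- function(object, empirical = NULL, ...) {
  p <- ggplot(object$levels, aes(x = .data$level, y = .data$prob)) +
    geom_col(fill = "grey70", width = 0.8) +
    labs(x = "difficulty level", y = "stationary probability",
         title = "Staircase level distribution") +
    theme_minimal()
  if (!is.null(empirical)) {
    p <- p + geom_point(data = empirical,
                        aes(x = .data$level, y = .data$freq),
                        colour = "firebrick", size = 2) +
      labs(subtitle = "bars: exact chain; points: closed-loop simulation")
  }
  p
}

#' Plot a questionnaire summary
#'
#' Yes/no items as percentage bars and Likert items as mean with one
#' standard error, side by side.
#'
#' @param object A `wm_questionnaire_summary`.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @method autoplot wm_questionnaire_summary
#' @export
autoplot.wm_questionnaire_summary <- function(object, ...) {
  p1 <- ggplot(object$yesno, aes(x = .data$question, y = .data$percent)) +
    geom_col(fill = "steelblue") +
    ylim(0, 100) +
    labs(x = NULL, y = "% yes", title = "Usability (yes/no)") +
    theme_minimal()
  p2 <- ggplot(object$likert, aes(x = .data$question, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.2) +
    ylim(0, 4) +
    labs(x = NULL, y = "mean score (1-4) ± SE",
         title = "Compliance (Likert)") +
    theme_minimal()
  patchwork::wrap_plots(p1, p2)
}
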