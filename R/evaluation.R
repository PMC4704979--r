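# Study outcome statistics: adherence summaries and the 9-item
# disposability-to-use questionnaire (5 yes/no items, 4 Likert items).

yesno_questions <- function() paste0("q", 1:5)
likert_questions <- function() paste0("q", 6:9)

as_yes <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("yes", "y", "true", "1")
}

check_questionnaire <- function(responses) {
  stopifnot(is.data.frame(responses))
  missing <- setdiff(c("patient_id", yesno_questions(), likert_questions()),
                     names(responses))
  if (length(missing) > 0) {
    abort_wm(paste0("questionnaire is missing columns: ",
                    paste(missing, collapse = ", ")), "wm_input_error")
  }
  for (q in likert_questions()) {
    if (!all(responses[[q]] %in% 1:4)) {
      abort_wm(sprintf("%s must contain Likert answers in 1..4 (1 = not at all, 4 = high)", q),
               "wm_input_error")
    }
  }
  responses
}

#' Summarize yes/no questionnaire items
#'
#' Counts "yes" answers per item and reports the percentage, rounded half
#' up to an integer (so 15 of 16 prints as 94%).
#'
#' @param responses Data frame with `patient_id`, yes/no columns `q1..q5`
#'   (logical, `"yes"`/`"no"` or 0/1) and Likert columns `q6..q9` (1–4).
#' @param question Item(s) to summarize; all five by default.
#' @return Tibble with `question`, `n_yes`, `n`, `percent`.
#' @examples
#' qs <- simulate_questionnaire(16, seed = 1)
#' summarize_yesno(qs)
#' @export
summarize_yesno <- function(responses, question = yesno_questions()) {
  check_questionnaire(responses)
  stopifnot(all(question %in% yesno_questions()))
  purrr::map_dfr(question, function(q) {
    yes <- as_yes(responses[[q]])
    n <- length(yes)
    if (n < 1) abort_wm("no responses", "wm_input_error")
    tibble::tibble(question = q, n_yes = sum(yes), n = n,
                   percent = round_half_up(100 * sum(yes) / n))
  })
}

#' Summarize Likert questionnaire items
#'
#' Arithmetic mean and standard error (sample standard deviation over
#' `sqrt(n)`) of the 1–4 answers per item.
#'
#' @inheritParams summarize_yesno
#' @return Tibble with `question`, `n`, `mean`, `se`.
#' @examples
#' qs <- simulate_questionnaire(16, seed = 1)
#' summarize_likert(qs)
#' @export
summarize_likert <- function(responses, question = likert_questions()) {
  check_questionnaire(responses)
  stopifnot(all(question %in% likert_questions()))
  purrr::map_dfr(question, function(q) {
    x <- as.numeric(responses[[q]])
    if (length(x) < 2) abort_wm("need at least 2 responses", "wm_input_error")
    tibble::tibble(question = q, n = length(x), mean = mean(x),
                   se = sd(x) / sqrt(length(x)))
  })
}

#' Summarize a whole questionnaire
#'
#' @inheritParams summarize_yesno
#' @return A `wm_questionnaire_summary`: list of the [summarize_yesno()]
#'   and [summarize_likert()] tibbles.
#' @export
summarize_questionnaire <- function(responses) {
  structure(list(yesno = summarize_yesno(responses),
                 likert = summarize_likert(responses),
                 n = nrow(responses)),
            class = "wm_questionnaire_summary")
}

#' @export
print.wm_questionnaire_summary <- function(x, ...) {
  cat(sprintf("<questionnaire summary, n = %d>\nYes/no items:\n", x$n))
  print(x$yesno)
  cat("Likert items (1 = not at all .. 4 = high):\n")
  print(x$likert)
  invisible(x)
}

#' Read / write questionnaire tables
#'
#' One row per patient, tab-separated, columns `patient_id`, `q1..q5`
#' (`yes`/`no`) and `q6..q9` (integers 1–4).
#'
#' @param path TSV file.
#' @return Tibble of responses (`q1..q5` as logical).
#' @export
read_questionnaire <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    .default = readr::col_guess()))
  for (q in yesno_questions()) raw[[q]] <- as_yes(raw[[q]])
  for (q in likert_questions()) raw[[q]] <- as.integer(raw[[q]])
  check_questionnaire(raw)
}

#' @rdname read_questionnaire
#' @param responses Questionnaire tibble.
#' @export
write_questionnaire <- function(responses, path) {
  check_questionnaire(responses)
  out <- responses
  for (q in yesno_questions()) {
    out[[q]] <- ifelse(as_yes(out[[q]]), "yes", "no")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Simulate a questionnaire cohort
#'
#' Draws yes/no answers as independent Bernoulli variables and Likert
#' answers from per-item categorical distributions over 1–4. The synthetic
#' fixture generator for the evaluation module.
#'
#' @param n Cohort size.
#' @param yes_prob Probability of "yes", recycled over `q1..q5`.
#' @param likert_prob Probabilities of answers 1–4, either one vector for
#'   all of `q6..q9` or a list named by question.
#' @param seed Integer seed.
#' @return Questionnaire tibble as read by [read_questionnaire()].
#' @examples
#' simulate_questionnaire(16, yes_prob = 0.9, seed = 7)
#' @export
simulate_questionnaire <- function(n, yes_prob = 0.85,
                                   likert_prob = c(0.1, 0.3, 0.4, 0.2),
                                   seed = 1L) {
  n <- check_count(n, "n", min = 1L)
  yes_prob <- rep(yes_prob, length.out = 5)
  if (!is.list(likert_prob)) {
    likert_prob <- stats::setNames(rep(list(likert_prob), 4),
                                   likert_questions())
  }
  withr::with_seed(seed, {
    out <- tibble::tibble(patient_id = sprintf("p%02d", seq_len(n)))
    for (i in seq_along(yesno_questions())) {
      out[[yesno_questions()[[i]]]] <- runif(n) < yes_prob[[i]]
    }
    for (q in likert_questions()) {
      pr <- likert_prob[[q]] / sum(likert_prob[[q]])
      out[[q]] <- sample.int(4L, n, replace = TRUE, prob = pr)
    }
    out
  })
}

#' Cohort adherence summary
#'
#' Applies the program's adherence accounting to a cohort: per-patient
#' completed-session counts, the cohort mean, the adherence percentage of
#' that mean, and the inclusion filter at the configured completion
#' fraction (patients below the session threshold are flagged excluded).
#'
#' @param completed Per-patient completed session counts: a numeric vector
#'   (optionally named), or a list of `wm_history` objects.
#' @param program A [training_program()].
#' @param inclusion_fraction Completion percentage required for inclusion
#'   in analysis (default 80).
#' @return A list of class `wm_adherence_summary`: `patients` tibble
#'   (`patient_id`, `sessions`, `adherence`, `included`), `mean_sessions`,
#'   `adherence_percent`, `threshold_sessions`.
#' @examples
#' adherence_summary(c(40, 33, 31), training_program())
#' @export
adherence_summary <- function(completed, program = program_preset(),
                              inclusion_fraction = 80) {
  if (is.list(completed) && all(purrr::map_lgl(completed, inherits, "wm_history"))) {
    ids <- purrr::map_chr(completed, "patient_id")
    completed <- stats::setNames(purrr::map_dbl(completed, ~ nrow(.x$sessions)), ids)
  }
  if (length(completed) == 0) abort_wm("no histories", "wm_input_error")
  ids <- names(completed) %||% sprintf("p%02d", seq_along(completed))
  threshold <- inclusion_threshold_sessions(program, inclusion_fraction)
  patients <- tibble::tibble(
    patient_id = ids,
    sessions = as.numeric(completed),
    adherence = adherence_percent(as.numeric(completed), program),
    included = completed >= threshold)
  structure(list(patients = patients,
                 mean_sessions = mean(patients$sessions),
                 adherence_percent = adherence_percent(mean(patients$sessions),
                                                       program),
                 threshold_sessions = threshold),
            class = "wm_adherence_summary")
}

#' @export
print.wm_adherence_summary <- function(x, ...) {
  cat(sprintf("<adherence: mean %.1f sessions, %d%% of schedule; inclusion needs >= %d sessions (%d/%d included)>\n",
              x$mean_sessions, x$adherence_percent, x$threshold_sessions,
              sum(x$patients$included), nrow(x$patients)))
  invisible(x)
}
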