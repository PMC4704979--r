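# Stimulus generation and scoring for the three working-memory paradigms:
# visuospatial span (vs_wm), operation N-back (op_nb), dual N-back (d_nb).

#' Stimuli per N-back block
#'
#' The protocol ties the number of stimuli presented in an N-back block to
#' the memory load: `(n_back + 1) * 5`. At N = 2 a block therefore presents
#' 15 stimuli, of which the last `15 - 2` are scored.
#'
#' @param n_back Non-negative integer memory load.
#' @return Integer number of stimuli in one block.
#' @examples
#' required_stimulus_count(2)
#' @export
required_stimulus_count <- function(n_back) {
  n_back <- check_count(n_back, "n_back", min = 0L)
  (n_back + 1L) * 5L
}

#' Exercise configurations
#'
#' Constructors for the parameter set of one exercise block. A configuration
#' is the unit the adaptive staircase manipulates: one stored record holds
#' exactly one configuration.
#'
#' * `vswm_config()` — visuospatial span: a `grid_rows` x `grid_cols` grid on
#'   which `sequence_length` distinct cells light up, one every `isi` seconds,
#'   to be reproduced in order.
#' * `opnb_config()` — operation N-back: pairs of digits in
#'   `[digit_lo, digit_hi]`; the response to each scored stimulus is the sum
#'   of the pair shown `n_back` stimuli earlier.
#' * `dnb_config()` — dual N-back: a digit 1–4 shown in one of 4 cells in a
#'   row; the response names both the digit and the cell `n_back` stimuli
#'   back.
#'
#' @param grid_rows,grid_cols Grid dimensions, each at least 2.
#' @param sequence_length Number of stimuli in a span sequence (>= 1, at most
#'   the number of grid cells: cells are drawn without replacement).
#' @param isi Inter-stimulus interval in seconds (> 0); the inverse of the
#'   presentation rate.
#' @param n_back Non-negative integer memory load.
#' @param digit_lo,digit_hi Inclusive digit span for operation N-back,
#'   within 1..9.
#' @param stimulus_count Stimuli per block; defaults to the protocol formula
#'   [required_stimulus_count()].
#' @return A config object (`vswm_config`, `opnb_config` or `dnb_config`),
#'   a list with class `wm_config`.
#' @examples
#' vswm_config(3, 3, sequence_length = 5, isi = 1.5)
#' opnb_config(n_back = 2) # 15 stimuli
#' @export
vswm_config <- function(grid_rows = 3, grid_cols = 3, sequence_length = 3,
                        isi = 2) {
  grid_rows <- check_count(grid_rows, "grid_rows", min = 2L)
  grid_cols <- check_count(grid_cols, "grid_cols", min = 2L)
  sequence_length <- check_count(sequence_length, "sequence_length", min = 1L)
  isi <- check_positive(isi, "isi")
  if (sequence_length > grid_rows * grid_cols) {
    abort_wm("sequence_length exceeds the number of grid cells (cells are sampled without replacement)",
             "wm_config_error")
  }
  structure(
    list(grid_rows = grid_rows, grid_cols = grid_cols,
         sequence_length = sequence_length, isi = isi),
    class = c("vswm_config", "wm_config")
  )
}

#' @rdname vswm_config
#' @export
opnb_config <- function(n_back = 0, digit_lo = 1, digit_hi = 9, isi = 4.5,
                        stimulus_count = required_stimulus_count(n_back)) {
  n_back <- check_count(n_back, "n_back", min = 0L)
  digit_lo <- check_count(digit_lo, "digit_lo", min = 1L)
  digit_hi <- check_count(digit_hi, "digit_hi", min = 1L)
  if (digit_lo > digit_hi || digit_hi > 9L) {
    abort_wm("digit span must satisfy 1 <= digit_lo <= digit_hi <= 9",
             "wm_config_error")
  }
  isi <- check_positive(isi, "isi")
  stimulus_count <- check_count(stimulus_count, "stimulus_count", min = 1L)
  structure(
    list(n_back = n_back, digit_lo = digit_lo, digit_hi = digit_hi,
         isi = isi, stimulus_count = stimulus_count),
    class = c("opnb_config", "wm_config")
  )
}

#' @rdname vswm_config
#' @export
dnb_config <- function(n_back = 0, isi = 4.5,
                       stimulus_count = required_stimulus_count(n_back)) {
  n_back <- check_count(n_back, "n_back", min = 0L)
  isi <- check_positive(isi, "isi")
  stimulus_count <- check_count(stimulus_count, "stimulus_count", min = 1L)
  structure(
    list(n_back = n_back, isi = isi, stimulus_count = stimulus_count),
    class = c("dnb_config", "wm_config")
  )
}

exercise_type_of <- function(config) {
  switch(class(config)[[1]],
         vswm_config = "vs_wm",
         opnb_config = "op_nb",
         dnb_config  = "d_nb",
         abort_wm("not an exercise config", "wm_domain_error"))
}

n_stimuli <- function(config) {
  if (inherits(config, "vswm_config")) config$sequence_length
  else config$stimulus_count
}

# scored positions: the whole sequence for vs_wm, the last count - N
# stimuli for the N-back paradigms (the first N are memorize-only)
n_scored <- function(config) {
  if (inherits(config, "vswm_config")) config$sequence_length
  else config$stimulus_count - config$n_back
}

new_stream <- function(exercise_type, items, seed, config, subclass) {
  structure(
    list(exercise_type = exercise_type, items = items,
         seed = as.integer(seed), config = config),
    class = c(subclass, "wm_stream")
  )
}

#' Generate a stimulus stream
#'
#' Draws one block's worth of stimuli from the configuration's stimulus
#' space under an explicit integer seed: identical `(config, seed)` always
#' yields an identical stream, and the seed is recorded on the stream (and
#' later in the raw log) so any block can be replayed.
#'
#' * visuospatial span: `sequence_length` grid cells sampled uniformly
#'   *without replacement* (the sequence never revisits a cell);
#' * operation N-back: `stimulus_count` digit pairs, each digit uniform and
#'   independent on the configured span;
#' * dual N-back: `stimulus_count` (digit, cell) pairs, digit uniform on
#'   1..4 and cell uniform on the 4 row positions, independent.
#'
#' @param config A config from [vswm_config()], [opnb_config()] or
#'   [dnb_config()].
#' @param seed Integer seed for this block.
#' @return A `wm_stream`: list with `exercise_type`, `items` (named list of
#'   aligned vectors; use [tibble::as_tibble()] for a tabular view), `seed`
#'   and `config`.
#' @examples
#' s <- generate_stream(vswm_config(3, 3, 5), seed = 7)
#' tibble::as_tibble(s)
#' @export
generate_stream <- function(config, seed) UseMethod("generate_stream")

#' @export
generate_stream.vswm_config <- function(config, seed) {
  cells <- withr::with_seed(
    as.integer(seed),
    sample.int(config$grid_rows * config$grid_cols, config$sequence_length,
               replace = FALSE)
  )
  new_stream("vs_wm", list(cell = cells), seed, config, "vswm_stream")
}

#' @export
generate_stream.opnb_config <- function(config, seed) {
  span <- config$digit_lo:config$digit_hi
  n <- config$stimulus_count
  items <- withr::with_seed(as.integer(seed), {
    d1 <- span[sample.int(length(span), n, replace = TRUE)]
    d2 <- span[sample.int(length(span), n, replace = TRUE)]
    list(d1 = d1, d2 = d2, sum = d1 + d2)
  })
  new_stream("op_nb", items, seed, config, "opnb_stream")
}

#' @export
generate_stream.dnb_config <- function(config, seed) {
  n <- config$stimulus_count
  items <- withr::with_seed(as.integer(seed), {
    list(digit = sample.int(4L, n, replace = TRUE),
         cell = sample.int(4L, n, replace = TRUE))
  })
  new_stream("d_nb", items, seed, config, "dnb_stream")
}

#' @method as_tibble wm_stream
#' @export
as_tibble.wm_stream <- function(x, ...) {
  tibble::as_tibble(c(list(position = seq_along(x$items[[1]])), x$items))
}

#' @export
print.wm_stream <- function(x, ...) {
  cat(sprintf("<wm_stream: %s, %d stimuli, seed %d>\n",
              x$exercise_type, length(x$items[[1]]), x$seed))
  print(tibble::as_tibble(x))
  invisible(x)
}

new_block_result <- function(exercise_type, n_correct, n_incorrect, n_missed,
                             level, timestamp) {
  n <- n_correct + n_incorrect + n_missed
  fast_row(
    list(exercise_type = exercise_type,
         n_correct = as.integer(n_correct),
         n_incorrect = as.integer(n_incorrect),
         n_missed = as.integer(n_missed),
         pct_correct = 100 * n_correct / n,
         level = as.integer(level),
         timestamp = timestamp),
    class = "wm_block_result"
  )
}

#' Score a response stream against a stimulus stream
#'
#' Compares responses position-by-position with the scored stimuli and
#' returns the block outcome: counts of correct, incorrect and missed
#' answers and the percentage of correct answers over all scored positions
#' (`pct_correct = 100 * n_correct / scored positions`), the quantity the
#' validity check consumes.
#'
#' Response encoding, one entry per *scored* position (`NA` = missed):
#'
#' * visuospatial span: integer vector of touched cell indices (1..cells),
#'   one per stimulus, order-sensitive with no partial credit;
#' * operation N-back: integer vector of sum-button values, aligned to
#'   stimuli `n_back + 1, ...`; correct iff equal to the digit-pair sum of
#'   the stimulus `n_back` back;
#' * dual N-back: data frame with `digit_button` (1–4) and `cell_button`
#'   (5–8, 5 = left-most cell), one row per scored position; an answer is
#'   correct only if *both* buttons match — a half-right answer counts as
#'   one incorrect answer. A row with any `NA` is a missed answer.
#'
#' @param stream A stream from [generate_stream()].
#' @param responses Responses encoded as above.
#' @param level Difficulty level of the record the block executed (stored in
#'   the result; `NA` outside an adaptive run).
#' @param timestamp Time of execution (`POSIXct`).
#' @return One-row tibble of class `wm_block_result` with columns
#'   `exercise_type`, `n_correct`, `n_incorrect`, `n_missed`, `pct_correct`,
#'   `level`, `timestamp`.
#' @examples
#' s <- generate_stream(vswm_config(2, 2, sequence_length = 4), seed = 1)
#' score_stream(s, s$items$cell) # perfect reproduction
#' @export
score_stream <- function(stream, responses, level = NA_integer_,
                         timestamp = Sys.time()) {
  UseMethod("score_stream")
}

tally_block <- function(exercise_type, correct, missed, level, timestamp) {
  new_block_result(exercise_type,
                   n_correct = sum(correct),
                   n_incorrect = sum(!correct & !missed),
                   n_missed = sum(missed),
                   level = level, timestamp = timestamp)
}

#' @export
score_stream.vswm_stream <- function(stream, responses, level = NA_integer_,
                                     timestamp = Sys.time()) {
  cfg <- stream$config
  if (length(responses) != cfg$sequence_length) {
    abort_wm("responses must have one entry per stimulus in the sequence",
             "wm_input_error")
  }
  n_cells <- cfg$grid_rows * cfg$grid_cols
  ok <- is.na(responses) | (responses %in% seq_len(n_cells))
  if (!all(ok)) {
    abort_wm("touched cell outside the grid", "wm_input_error")
  }
  missed <- is.na(responses)
  correct <- !missed & responses == stream$items$cell
  tally_block("vs_wm", correct, missed, level, timestamp)
}

#' @export
score_stream.opnb_stream <- function(stream, responses, level = NA_integer_,
                                     timestamp = Sys.time()) {
  cfg <- stream$config
  n <- n_scored(cfg)
  if (n < 1) {
    abort_wm("n_back >= stimulus_count leaves no scorable position",
             "wm_config_error")
  }
  if (length(responses) != n) {
    abort_wm(sprintf("expected %d responses (stimulus_count - n_back)", n),
             "wm_input_error")
  }
  truth <- stream$items$sum[seq_len(n)] # sum of the stimulus n_back before each scored one
  missed <- is.na(responses)
  correct <- !missed & responses == truth
  tally_block("op_nb", correct, missed, level, timestamp)
}

#' @export
score_stream.dnb_stream <- function(stream, responses, level = NA_integer_,
                                    timestamp = Sys.time()) {
  cfg <- stream$config
  n <- n_scored(cfg)
  if (n < 1) {
    abort_wm("n_back >= stimulus_count leaves no scorable position",
             "wm_config_error")
  }
  responses <- as.data.frame(responses)
  if (nrow(responses) != n ||
      !all(c("digit_button", "cell_button") %in% names(responses))) {
    abort_wm(sprintf(
      "expected a data frame of %d rows with digit_button and cell_button", n),
      "wm_input_error")
  }
  db <- responses$digit_button
  cb <- responses$cell_button
  missed <- is.na(db) | is.na(cb)
  if (!all(db[!missed] %in% 1:4)) {
    abort_wm("digit_button outside 1..4", "wm_input_error")
  }
  if (!all(cb[!missed] %in% 5:8)) {
    abort_wm("cell_button outside 5..8", "wm_input_error")
  }
  truth_digit <- stream$items$digit[seq_len(n)]
  truth_cell <- stream$items$cell[seq_len(n)]
  # both touches form one answer: digit must match AND cell button (5..8,
  # left to right) must name the stimulus cell; half-right is incorrect
  correct <- !missed & db == truth_digit & (cb - 4L) == truth_cell
  tally_block("d_nb", correct, missed, level, timestamp)
}
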