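# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (explicit loops over the task rules) so
# they share no code with the implementation they check.

# Brute-force scorer: walks scored positions one by one and applies the
# task rule literally. `truth` is a list of the expected answers, one per
# scored position; `answers` a list of given answers (NULL = missed).
brute_force_score <- function(truth, answers, same = identical) {
  n_correct <- 0L; n_incorrect <- 0L; n_missed <- 0L
  for (i in seq_along(truth)) {
    a <- answers[[i]]
    if (is.null(a) || (length(a) > 0 && any(is.na(a)))) {
      n_missed <- n_missed + 1L
    } else if (same(a, truth[[i]])) {
      n_correct <- n_correct + 1L
    } else {
      n_incorrect <- n_incorrect + 1L
    }
  }
  list(n_correct = n_correct, n_incorrect = n_incorrect, n_missed = n_missed,
       pct_correct = 100 * n_correct / length(truth))
}

# Replay oracle for the staircase: recomputes the level trajectory from a
# valid/invalid string by literal reading of the rule — +1 on every valid
# block; watch for three invalid blocks in a row since the last level
# change, then -1 (never below the floor).
replay_levels_oracle <- function(valids, floor = 1L, ceiling = Inf) {
  level <- 1L
  run <- 0L
  levels <- integer(length(valids))
  for (i in seq_along(valids)) {
    levels[[i]] <- level
    if (valids[[i]]) {
      level <- as.integer(min(level + 1L, ceiling))
      run <- 0L
    } else {
      run <- run + 1L
      if (run == 3L) {
        level <- as.integer(max(level - 1L, floor))
        run <- 0L
      }
    }
  }
  list(levels = levels, final = level)
}

# enumerate all length-n TRUE/FALSE vectors
all_bool_strings <- function(n) {
  if (n == 0) return(list(logical(0)))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))
  lapply(seq_len(nrow(grid)), function(i) as.logical(unlist(grid[i, ])))
}

# batch-means Monte-Carlo standard error of a frequency, honest about the
# autocorrelation of the staircase chain
batch_se <- function(indicator, n_batches = 20) {
  n <- length(indicator)
  batch <- rep(seq_len(n_batches), each = ceiling(n / n_batches))[seq_len(n)]
  means <- tapply(indicator, batch, mean)
  stats::sd(means) / sqrt(length(means))
}

expect_counts <- function(result, correct, incorrect, missed) {
  expect_equal(result$n_correct, correct)
  expect_equal(result$n_incorrect, incorrect)
  expect_equal(result$n_missed, missed)
  expect_equal(result$pct_correct,
               100 * correct / (correct + incorrect + missed))
}
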