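# Stimulus generation and scoring for the three paradigms.

test_that("stimulus-count formula follows (N+1)x5", {
  expect_identical(required_stimulus_count(2), 15L)
  expect_identical(required_stimulus_count(0), 5L)
  expect_identical(required_stimulus_count(4), 25L)
  expect_error(required_stimulus_count(-1), class = "wm_domain_error")
})

test_that("config invariants are enforced", {
  expect_error(vswm_config(1, 3), class = "wm_domain_error")        # grid >= 2x2
  expect_error(vswm_config(2, 2, sequence_length = 5),
               class = "wm_config_error")                           # > cells
  expect_error(vswm_config(3, 3, isi = 0), class = "wm_config_error")
  expect_error(opnb_config(digit_lo = 0), class = "wm_domain_error")
  expect_error(opnb_config(digit_lo = 5, digit_hi = 3),
               class = "wm_config_error")
  expect_error(opnb_config(digit_hi = 10), class = "wm_config_error")
  expect_identical(opnb_config(n_back = 2)$stimulus_count, 15L)
  expect_identical(dnb_config(n_back = 1)$stimulus_count, 10L)
})

test_that("generators are deterministic under a fixed seed", {
  for (cfg in list(vswm_config(3, 3, 5), opnb_config(n_back = 1),
                   dnb_config(n_back = 2))) {
    s1 <- generate_stream(cfg, 7)
    s2 <- generate_stream(cfg, 7)
    s3 <- generate_stream(cfg, 8)
    expect_identical(s1, s2)
    expect_false(identical(s1$items, s3$items))
  }
})

test_that("span sequences sample the grid without replacement", {
  # a 2x2 grid with sequence length 4 must exhaust the grid
  for (seed in 1:25) {
    s <- generate_stream(vswm_config(2, 2, sequence_length = 4), seed)
    expect_setequal(s$items$cell, 1:4)
  }
  s <- generate_stream(vswm_config(4, 4, sequence_length = 10), 3)
  expect_identical(anyDuplicated(s$items$cell), 0L)
})

test_that("single-stimulus span draws are uniform over the grid (binomial oracle)", {
  n <- 10000
  cfg <- vswm_config(3, 3, sequence_length = 1)
  cells <- vapply(seq_len(n), function(i) {
    generate_stream(cfg, i)$items$cell
  }, 1L)
  p <- 1 / 9
  sd3 <- 3 * sqrt(p * (1 - p) * n)
  counts <- tabulate(cells, nbins = 9)
  expect_true(all(abs(counts - n * p) <= sd3))
})

test_that("dual N-back items stay in their domain and are uniform", {
  s <- generate_stream(dnb_config(n_back = 1, stimulus_count = 10000), 11)
  expect_true(all(s$items$digit %in% 1:4))
  expect_true(all(s$items$cell %in% 1:4))
  n <- 10000
  sd3 <- 3 * sqrt(0.25 * 0.75 * n)
  expect_true(all(abs(tabulate(s$items$digit, 4) - n / 4) <= sd3))
  expect_true(all(abs(tabulate(s$items$cell, 4) - n / 4) <= sd3))
})

test_that("operation N-back sums over the full digit span cover exactly 2..18", {
  pairs <- expand.grid(d1 = 1:9, d2 = 1:9)
  sums <- pairs$d1 + pairs$d2
  expect_identical(range(sums), c(2L, 18L))
  s <- generate_stream(opnb_config(n_back = 0, stimulus_count = 500), 5)
  expect_true(all(s$items$sum >= 2 & s$items$sum <= 18))
  # degenerate span: every pair is (3,3)
  s3 <- generate_stream(opnb_config(digit_lo = 3, digit_hi = 3), 1)
  expect_true(all(s3$items$d1 == 3 & s3$items$d2 == 3 & s3$items$sum == 6))
})

test_that("span scoring is order-sensitive, position by position", {
  cfg <- vswm_config(3, 3, sequence_length = 4)
  s <- generate_stream(cfg, 2)
  truth <- s$items$cell
  expect_counts(score_stream(s, truth), 4L, 0L, 0L)
  # two right, one wrong cell, one missed -> pct 50
  wrong <- setdiff(1:9, truth)[1]
  expect_counts(score_stream(s, c(truth[1:2], wrong, NA)), 2L, 1L, 1L)
  # right cells in the wrong order earn nothing
  s2 <- generate_stream(vswm_config(3, 3, sequence_length = 2), 4)
  expect_counts(score_stream(s2, rev(s2$items$cell)), 0L, 2L, 0L)
  # all missed -> pct 0
  s1 <- generate_stream(vswm_config(2, 2, sequence_length = 1), 9)
  expect_identical(score_stream(s1, NA_integer_)$pct_correct, 0)
  expect_error(score_stream(s, truth[1:3]), class = "wm_input_error")
  expect_error(score_stream(s, c(truth[1:3], 10L)), class = "wm_input_error")
})

make_opnb_stream <- function(d1, d2, n_back) {
  cfg <- opnb_config(n_back = n_back, stimulus_count = length(d1))
  s <- generate_stream(cfg, 1)
  s$items <- list(d1 = d1, d2 = d2, sum = d1 + d2)
  s
}

test_that("operation N-back answers are sums deferred by N stimuli", {
  # N=0: answer the sum of the current pair
  s <- make_opnb_stream(1L, 4L, 0L)
  expect_counts(score_stream(s, 5L), 1L, 0L, 0L)
  # N=1 over (1,4),(2,3),(5,2): scored answers are sums of stimuli 1 and 2
  s <- make_opnb_stream(c(1L, 2L, 5L), c(4L, 3L, 2L), 1L)
  expect_counts(score_stream(s, c(5L, 5L)), 2L, 0L, 0L)
  expect_counts(score_stream(s, c(5L, 7L)), 1L, 1L, 0L)
  # a missed answer scores as missed, not incorrect
  s <- make_opnb_stream(c(1L, 2L), c(4L, 3L), 1L)
  expect_counts(score_stream(s, NA_integer_), 0L, 0L, 1L)
  expect_error(score_stream(s, c(5L, 5L)), class = "wm_input_error")
})

make_dnb_stream <- function(digit, cell, n_back) {
  cfg <- dnb_config(n_back = n_back, stimulus_count = length(digit))
  s <- generate_stream(cfg, 1)
  s$items <- list(digit = digit, cell = cell)
  s
}

test_that("dual N-back requires both the digit and the cell button", {
  # digit 3 in the second cell: buttons (3, 6) are right, (3, 7) is not
  s <- make_dnb_stream(3L, 2L, 0L)
  expect_counts(score_stream(s, data.frame(digit_button = 3L, cell_button = 6L)),
                1L, 0L, 0L)
  expect_counts(score_stream(s, data.frame(digit_button = 3L, cell_button = 7L)),
                0L, 1L, 0L)
  expect_counts(score_stream(s, data.frame(digit_button = 2L, cell_button = 6L)),
                0L, 1L, 0L)
  # N=1: the single scored answer refers to the first stimulus
  s <- make_dnb_stream(c(1L, 2L), c(1L, 3L), 1L)
  expect_counts(score_stream(s, data.frame(digit_button = 1L, cell_button = 5L)),
                1L, 0L, 0L)
  expect_error(
    score_stream(s, data.frame(digit_button = 5L, cell_button = 6L)),
    class = "wm_input_error")
  expect_error(
    score_stream(s, data.frame(digit_button = 1L, cell_button = 4L)),
    class = "wm_input_error")
})

test_that("every scorer conserves counts and recomputes pct from them", {
  set.seed(42)
  for (rep in 1:20) {
    cfg <- vswm_config(3, 3, sequence_length = sample(1:9, 1))
    s <- generate_stream(cfg, rep)
    resp <- ifelse(runif(cfg$sequence_length) < 0.2, NA_integer_,
                   sample.int(9L, cfg$sequence_length, replace = TRUE))
    r <- score_stream(s, resp)
    expect_identical(r$n_correct + r$n_incorrect + r$n_missed,
                     cfg$sequence_length)
    expect_identical(r$pct_correct,
                     100 * r$n_correct / cfg$sequence_length)

    nb <- sample(0:2, 1)
    cfg <- opnb_config(n_back = nb)
    s <- generate_stream(cfg, rep)
    n <- cfg$stimulus_count - nb
    resp <- ifelse(runif(n) < 0.2, NA_integer_,
                   sample(2:18, n, replace = TRUE))
    r <- score_stream(s, resp)
    expect_identical(r$n_correct + r$n_incorrect + r$n_missed, n)
    expect_identical(r$pct_correct, 100 * r$n_correct / n)
  }
})

test_that("scorers agree with brute-force enumeration on small blocks", {
  # span: 2x2 grid, sequences of length 1..3, every response assignment
  # over {cells 1..4, MISSED}
  for (len in 1:3) {
    s <- generate_stream(vswm_config(2, 2, sequence_length = len), len)
    grid <- expand.grid(rep(list(c(1:4, NA)), len))
    for (i in seq_len(nrow(grid))) {
      resp <- as.integer(unlist(grid[i, ]))
      got <- score_stream(s, resp)
      want <- brute_force_score(as.list(s$items$cell),
                                lapply(resp, function(a) if (is.na(a)) NULL else a))
      expect_counts(got, want$n_correct, want$n_incorrect, want$n_missed)
    }
  }
  # operation 1-back: digit span 1..2, 4 stimuli, answers over {2,3,4,MISSED}
  s <- generate_stream(opnb_config(n_back = 1, digit_lo = 1, digit_hi = 2,
                                   stimulus_count = 4), 9)
  grid <- expand.grid(rep(list(c(2:4, NA)), 3))
  truth <- as.list(s$items$sum[1:3])
  for (i in seq_len(nrow(grid))) {
    resp <- as.integer(unlist(grid[i, ]))
    got <- score_stream(s, resp)
    want <- brute_force_score(truth,
                              lapply(resp, function(a) if (is.na(a)) NULL else a))
    expect_counts(got, want$n_correct, want$n_incorrect, want$n_missed)
  }
  # dual 1-back: 3 stimuli, both-button answers over a reduced alphabet
  s <- generate_stream(dnb_config(n_back = 1, stimulus_count = 3), 13)
  alphabet <- c(list(NULL), lapply(seq_len(8), function(k) {
    c((k - 1) %% 4 + 1, (k - 1) %/% 4 + 5) # (digit, cell-button) pairs
  }))
  idx <- expand.grid(a1 = seq_along(alphabet), a2 = seq_along(alphabet))
  truth <- lapply(1:2, function(j) c(s$items$digit[j], s$items$cell[j] + 4))
  for (i in seq_len(nrow(idx))) {
    answers <- list(alphabet[[idx$a1[i]]], alphabet[[idx$a2[i]]])
    resp <- data.frame(
      digit_button = vapply(answers, function(a) if (is.null(a)) NA_integer_ else as.integer(a[1]), 1L),
      cell_button = vapply(answers, function(a) if (is.null(a)) NA_integer_ else as.integer(a[2]), 1L))
    got <- score_stream(s, resp)
    want <- brute_force_score(truth, answers)
    expect_counts(got, want$n_correct, want$n_incorrect, want$n_missed)
  }
})
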