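# Store integrity, raw-log round trips, reports, export/import bundles.

fresh_store <- function() wm_store(withr::local_tempdir(.local_envir = parent.frame()))

test_that("upserts round-trip, are idempotent, and enforce foreign keys", {
  st <- fresh_store()
  upsert_patient(st, "p1", name = "Patient One", metadata = "EDSS=3.5")
  expect_identical(st$patients$name[st$patients$patient_id == "p1"],
                   "Patient One")
  # re-upsert with the same key: still one row, new values win
  upsert_patient(st, "p1", name = "Patient 1")
  expect_identical(nrow(st$patients), 1L)
  expect_identical(st$patients$name, "Patient 1")

  lad <- difficulty_ladder("vs_wm")
  rec <- starting_record("r1", "p1", lad)
  upsert_record(st, rec)
  back <- get_record(st, "r1")
  expect_identical(back$config, rec$config)
  expect_identical(back$level, rec$level)
  # dangling foreign keys are refused
  expect_error(upsert_record(st, starting_record("r2", "ghost", lad)),
               class = "wm_integrity_error")
  expect_error(upsert_assignment(st, "a1", "p1", "missing-record"),
               class = "wm_integrity_error")
  expect_error(upsert_assignment(st, "a1", "ghost", "r1"),
               class = "wm_integrity_error")
  upsert_assignment(st, "a1", "p1", "r1", ordinal = 1, adaptive_enabled = TRUE)
  expect_identical(nrow(st$assignments), 1L)
  expect_error(get_record(st, "nope"), class = "wm_lookup_error")
})

test_that("auto-generated records cannot be assigned to another patient", {
  st <- fresh_store()
  upsert_patient(st, "p1")
  upsert_patient(st, "p2")
  lad <- difficulty_ladder("op_nb")
  rec <- starting_record("r1", "p1", lad)
  upsert_record(st, rec)
  spawned <- spawn_record(rec, advance_state(adaptive_state(), TRUE), lad,
                          record_id = "r2")
  upsert_record(st, spawned)
  upsert_assignment(st, "a1", "p1", "r2") # own patient: fine
  expect_error(upsert_assignment(st, "a2", "p2", "r2"),
               class = "wm_integrity_error")
  # a manually created (non-auto) record may be shared
  upsert_assignment(st, "a3", "p2", "r1")
  expect_identical(nrow(st$assignments), 2L)
})

test_that("config serialization is an exact inverse for all three types", {
  configs <- list(vswm_config(3, 4, 7, isi = 1.75),
                  opnb_config(2, 1, 9, isi = 3.5),
                  dnb_config(3, isi = 3, stimulus_count = 20))
  for (cfg in configs) {
    expect_identical(parse_config(serialize_config(cfg)), cfg)
  }
})

log_some_blocks <- function(path, n, patient = "p1", seed0 = 100) {
  lad <- difficulty_ladder("d_nb")
  model <- responder_model(capacity = 3)
  rec <- starting_record("r1", patient, lad)
  for (i in seq_len(n)) {
    res <- run_block(model, rec, seed0 + i,
                     timestamp = as.POSIXct("2012-03-01 09:00:00", tz = "UTC") + i)
    append_raw_log(res, rec, path, seed = seed0 + i,
                   valid = evaluate_validity(res))
  }
}

test_that("raw-log writer and reader are exact inverses, order preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lad <- difficulty_ladder("vs_wm")
  rec <- starting_record("r1", "p1", lad)
  s <- generate_stream(rec$config, 5)
  resp <- s$items$cell
  resp[2] <- NA
  res <- score_stream(s, resp, level = 1L,
                      timestamp = as.POSIXct("2012-03-01 10:30:00", tz = "UTC"))
  line <- append_raw_log(res, rec, path, seed = 5,
                         valid = evaluate_validity(res))
  back <- read_raw_log(path)
  expect_identical(nrow(back), 1L)
  expect_identical(as.data.frame(back), as.data.frame(line))
  expect_identical(back$timestamp, "2012-03-01T10:30:00")
  expect_identical(back$pct_correct, 100 * 2 / 3)
  expect_identical(back$seed, 5L)
  expect_identical(parse_config(back$config), rec$config)

  # 100 appends -> 100 lines in order
  path2 <- withr::local_tempfile(fileext = ".tsv")
  log_some_blocks(path2, 100)
  full <- read_raw_log(path2)
  expect_identical(nrow(full), 100L)
  expect_identical(full$seed, 101:200)
  expect_identical(full$n_correct + full$n_incorrect + full$n_missed,
                   rep(5L, 100))
})

test_that("malformed log lines are flagged with their line numbers, others parse", {
  path <- withr::local_tempfile(fileext = ".tsv")
  log_some_blocks(path, 3)
  lines <- readLines(path)
  lines[3] <- "corrupted\tline"
  writeLines(lines, path)
  expect_warning(back <- read_raw_log(path), "line 3")
  expect_identical(nrow(back), 2L)
  bad <- attr(back, "bad_lines")
  expect_identical(bad$line, 3L)
})

test_that("reports recompute the processed view from the raw log", {
  st <- fresh_store()
  upsert_patient(st, "p1")
  lad <- difficulty_ladder("op_nb")
  model <- responder_model(capacity = 5, p_high = 1, miss_rate = 0)
  state <- adaptive_state()
  rec <- starting_record("r1", "p1", lad)
  upsert_record(st, rec)
  for (i in 1:3) {
    res <- run_block(model, rec, i,
                     timestamp = as.POSIXct("2012-03-01 09:00:00", tz = "UTC") + i)
    valid <- evaluate_validity(res)
    append_raw_log(res, rec, st$log_path, seed = i, valid = valid)
    state <- advance_state(state, valid)
    nxt <- spawn_record(rec, state, lad, record_id = paste0("r", i + 1))
    if (!is.null(nxt)) {
      rec <- nxt
      upsert_record(st, rec)
    }
  }
  rep <- generate_report(st, "p1")
  expect_identical(nrow(rep$blocks), 3L)
  expect_identical(rep$blocks$level, 1:3) # a perfect responder climbs each block
  expect_identical(rep$max_levels$max_level, 3L)
  expect_true(all(rep$blocks$n_correct + rep$blocks$n_incorrect +
                    rep$blocks$n_missed == 5L))
  expect_identical(glance(rep)$max_level_op_nb, 3L)

  # empty report for a patient with no blocks
  upsert_patient(st, "p2")
  empty <- generate_report(st, "p2")
  expect_identical(nrow(empty$blocks), 0L)
  expect_identical(nrow(empty$max_levels), 0L)
  expect_error(generate_report(st, "ghost"), class = "wm_lookup_error")
})

test_that("export and import round-trip a store, checksums catch tampering", {
  st <- fresh_store()
  upsert_patient(st, "p1", name = "One")
  lad <- difficulty_ladder("vs_wm")
  upsert_record(st, starting_record("r1", "p1", lad))
  upsert_assignment(st, "a1", "p1", "r1", adaptive_enabled = TRUE)
  set_settings(st, user_mode = TRUE)
  log_some_blocks(st$log_path, 10)

  dest <- withr::local_tempdir()
  export_bundle(st, dest, overwrite = TRUE)
  st2 <- import_bundle(dest, dir = withr::local_tempdir())
  for (tab in c("patients", "records", "assignments", "settings")) {
    expect_equal(as.data.frame(st2[[tab]]), as.data.frame(st[[tab]]))
  }
  expect_identical(readLines(st2$log_path), readLines(st$log_path))

  # empty store exports and re-imports cleanly
  empty <- fresh_store()
  dest2 <- withr::local_tempdir()
  export_bundle(empty, dest2, overwrite = TRUE)
  st3 <- import_bundle(dest2, dir = withr::local_tempdir())
  expect_identical(nrow(st3$patients), 0L)

  # tampering with an exported file fails the checksum on import
  log_file <- file.path(dest, "raw_log.tsv")
  writeLines(c(readLines(log_file), "tampered"), log_file)
  expect_error(import_bundle(dest), class = "wm_integrity_error")
})
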