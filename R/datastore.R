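# Persistence: a three-section relational-style store (patients; records
# and treatment assignments; settings), the append-only tab-separated raw
# trial log, per-patient reports, and an export/import bundle.

#' Create a store
#'
#' An in-memory store of three sections mirrored on disk through
#' [export_bundle()] / [import_bundle()]: `patients`, `records` +
#' `assignments` (exercises and treatments), and `settings` (a single
#' active row). Every table is keyed by a unique primary key and foreign
#' keys are checked on every upsert. Raw per-block logs append to
#' `log_path` (see [append_raw_log()]).
#'
#' @param dir Directory for the store's raw log (created if missing;
#'   a fresh temporary directory by default).
#' @return A `wm_store` environment.
#' @export
wm_store <- function(dir = tempfile("wm_store_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  store <- new.env(parent = emptyenv())
  store$patients <- tibble::tibble(patient_id = character(),
                                   name = character(),
                                   metadata = character())
  store$records <- tibble::tibble(record_id = character(),
                                  patient_id = character(),
                                  exercise_type = character(),
                                  level = integer(),
                                  auto_generated = logical(),
                                  parent_record_id = character(),
                                  config = character())
  store$assignments <- tibble::tibble(assignment_id = character(),
                                      patient_id = character(),
                                      record_id = character(),
                                      ordinal = integer(),
                                      adaptive_enabled = logical())
  store$settings <- tibble::tibble(user_mode = logical(),
                                   program_name = character(),
                                   thresholds = character())
  store$dir <- dir
  store$log_path <- file.path(dir, "raw_log.tsv")
  class(store) <- "wm_store"
  store
}

#' @export
print.wm_store <- function(x, ...) {
  cat(sprintf("<wm_store: %d patients, %d records, %d assignments, log %s>\n",
              nrow(x$patients), nrow(x$records), nrow(x$assignments),
              if (file.exists(x$log_path)) basename(x$log_path) else "(empty)"))
  invisible(x)
}

upsert_row <- function(store, table, row, key) {
  tab <- store[[table]]
  tab <- tab[tab[[key]] != row[[key]], , drop = FALSE]
  store[[table]] <- dplyr::bind_rows(tab, row)
  row
}

#' Store upserts
#'
#' Insert or replace one row of a store section, enforcing unique primary
#' keys and referential integrity (an assignment must name an existing
#' patient and record; a patient-bound record must name an existing
#' patient; an auto-generated record can only ever be assigned to the
#' patient it was spawned for).
#'
#' @param store A [wm_store()].
#' @param patient_id,name,metadata Patient key and opaque descriptive text
#'   (clinical metadata is stored uninterpreted).
#' @return The stored row, invisibly.
#' @export
upsert_patient <- function(store, patient_id, name = NA_character_,
                           metadata = NA_character_) {
  stopifnot(inherits(store, "wm_store"))
  row <- tibble::tibble(patient_id = as.character(patient_id),
                        name = as.character(name),
                        metadata = as.character(metadata))
  invisible(upsert_row(store, "patients", row, "patient_id"))
}

#' @rdname upsert_patient
#' @param record A [exercise_record()].
#' @export
upsert_record <- function(store, record) {
  stopifnot(inherits(store, "wm_store"), inherits(record, "wm_record"))
  if (!is.na(record$patient_id) &&
      !record$patient_id %in% store$patients$patient_id) {
    abort_wm(sprintf("record references unknown patient '%s'",
                     record$patient_id), "wm_integrity_error")
  }
  row <- tibble::tibble(record_id = record$record_id,
                        patient_id = record$patient_id,
                        exercise_type = record$exercise_type,
                        level = record$level,
                        auto_generated = record$auto_generated,
                        parent_record_id = record$parent_record_id,
                        config = serialize_config(record$config))
  invisible(upsert_row(store, "records", row, "record_id"))
}

#' @rdname upsert_patient
#' @param assignment_id,record_id,ordinal,adaptive_enabled Assignment key,
#'   the assigned record, its position in the treatment plan, and whether
#'   the adaptive staircase drives subsequent records (in which case only
#'   the starting record is administrator-assigned).
#' @export
upsert_assignment <- function(store, assignment_id, patient_id, record_id,
                              ordinal = NA_integer_, adaptive_enabled = FALSE) {
  stopifnot(inherits(store, "wm_store"))
  if (!patient_id %in% store$patients$patient_id) {
    abort_wm(sprintf("assignment references unknown patient '%s'", patient_id),
             "wm_integrity_error")
  }
  rec <- store$records[store$records$record_id == record_id, ]
  if (nrow(rec) == 0) {
    abort_wm(sprintf("assignment references unknown record '%s'", record_id),
             "wm_integrity_error")
  }
  if (rec$auto_generated && !identical(rec$patient_id, as.character(patient_id))) {
    abort_wm("auto-generated records are bound to their patient and cannot be assigned to another subject",
             "wm_integrity_error")
  }
  row <- tibble::tibble(assignment_id = as.character(assignment_id),
                        patient_id = as.character(patient_id),
                        record_id = as.character(record_id),
                        ordinal = as.integer(ordinal),
                        adaptive_enabled = isTRUE(adaptive_enabled))
  invisible(upsert_row(store, "assignments", row, "assignment_id"))
}

#' @rdname upsert_patient
#' @param user_mode `TRUE` for USER modality (restricted, patient-facing),
#'   `FALSE` for ADMIN modality; a flag only.
#' @param program_name Name of the active program preset.
#' @param thresholds A [validity_thresholds()].
#' @export
set_settings <- function(store, user_mode = FALSE,
                         program_name = "takeuchi-8w",
                         thresholds = validity_thresholds()) {
  stopifnot(inherits(store, "wm_store"))
  store$settings <- tibble::tibble(
    user_mode = isTRUE(user_mode),
    program_name = as.character(program_name),
    thresholds = paste(sprintf("%s=%s", names(unclass(thresholds)),
                               vapply(unclass(thresholds), num_chr, "")),
                       collapse = ";"))
  invisible(store$settings)
}

#' Fetch a record back as a `wm_record`
#'
#' @param store A [wm_store()].
#' @param record_id Primary key.
#' @return The `wm_record` (config deserialized).
#' @export
get_record <- function(store, record_id) {
  row <- store$records[store$records$record_id == record_id, ]
  if (nrow(row) == 0) {
    abort_wm(sprintf("no record '%s'", record_id), "wm_lookup_error")
  }
  exercise_record(row$record_id, row$patient_id,
                  parse_config(row$config),
                  level = row$level,
                  auto_generated = row$auto_generated,
                  parent_record_id = row$parent_record_id)
}

# shortest decimal string that round-trips the double exactly
num_chr <- function(x) {
  s <- as.character(x)
  ifelse(is.na(x) | as.numeric(s) == x, s, sprintf("%.17g", x))
}

#' Serialize / parse an exercise configuration
#'
#' Key-value text (`type=vs_wm;grid_rows=3;...`) used in the raw log and
#' the records table; `parse_config()` is its exact inverse.
#'
#' @param config A `wm_config`.
#' @param text A string produced by `serialize_config()`.
#' @return A string, resp. the reconstructed config.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "wm_config"))
  vals <- vapply(config, num_chr, "")
  paste(c(paste0("type=", exercise_type_of(config)),
          sprintf("%s=%s", names(config), vals)), collapse = ";")
}

#' @rdname serialize_config
#' @export
parse_config <- function(text) {
  kv <- strsplit(strsplit(text, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  type <- vals[["type"]]
  num <- function(k) as.numeric(vals[[k]])
  switch(type,
         vs_wm = vswm_config(num("grid_rows"), num("grid_cols"),
                             num("sequence_length"), num("isi")),
         op_nb = opnb_config(num("n_back"), num("digit_lo"), num("digit_hi"),
                             num("isi"), num("stimulus_count")),
         d_nb = dnb_config(num("n_back"), num("isi"), num("stimulus_count")),
         abort_wm(sprintf("unknown config type '%s'", type), "wm_domain_error"))
}

raw_log_columns <- function() {
  c("timestamp", "patient_id", "exercise_type", "level", "config", "seed",
    "n_correct", "n_incorrect", "n_missed", "pct_correct", "valid")
}

format_timestamp <- function(x) {
  if (inherits(x, "POSIXt")) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  else as.character(x)
}

#' Append one block to the raw log
#'
#' Writes exactly one tab-separated line per executed block to the
#' append-only raw log (UTF-8, one header line, ISO-8601 timestamps). The
#' line carries everything needed to replay the block — config snapshot and
#' stimulus seed — alongside the outcome counts and validity flag, and
#' round-trips losslessly through [read_raw_log()].
#'
#' @param result A `wm_block_result`.
#' @param record The `wm_record` the block executed.
#' @param path Log file (created with a header on first write); defaults
#'   to the store's log when a store is given.
#' @param seed Stimulus seed of the block.
#' @param valid Validity flag from [evaluate_validity()].
#' @return The appended line parsed back, as a one-row tibble.
#' @export
append_raw_log <- function(result, record, path, seed = NA_integer_,
                           valid = NA) {
  stopifnot(inherits(result, "wm_block_result"), inherits(record, "wm_record"))
  fields <- c(format_timestamp(result$timestamp),
              record$patient_id,
              result$exercise_type,
              as.character(result$level),
              serialize_config(record$config),
              as.character(as.integer(seed)),
              as.character(result$n_correct),
              as.character(result$n_incorrect),
              as.character(result$n_missed),
              num_chr(result$pct_correct),
              as.character(valid))
  line <- paste(fields, collapse = "\t")
  if (!file.exists(path)) {
    readr::write_lines(paste(raw_log_columns(), collapse = "\t"), path)
  }
  readr::write_lines(line, path, append = TRUE)
  parse_log_lines(line, 2L)$lines
}

parse_log_lines <- function(lines, start_no) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == length(raw_log_columns())
  mat <- do.call(rbind, parts[ok])
  out <- if (is.null(mat)) {
    tibble::as_tibble(stats::setNames(
      rep(list(character()), length(raw_log_columns())), raw_log_columns()))
  } else {
    tibble::as_tibble(stats::setNames(as.data.frame(mat,
                                                    stringsAsFactors = FALSE),
                                      raw_log_columns()))
  }
  out$level <- as.integer(out$level)
  out$seed <- as.integer(out$seed)
  out$n_correct <- as.integer(out$n_correct)
  out$n_incorrect <- as.integer(out$n_incorrect)
  out$n_missed <- as.integer(out$n_missed)
  out$pct_correct <- as.numeric(out$pct_correct)
  out$valid <- as.logical(out$valid)
  list(lines = out,
       bad = tibble::tibble(line = start_no - 1L + which(!ok),
                            content = lines[!ok]))
}

#' Read a raw log
#'
#' Parses every well-formed line; malformed lines are reported with their
#' line numbers in a warning and in the `bad_lines` attribute, and do not
#' prevent the rest of the file from loading.
#'
#' @param path Log file written by [append_raw_log()].
#' @return Tibble with one row per block (columns as documented for
#'   [append_raw_log()]); attribute `bad_lines` lists rejected lines.
#' @export
read_raw_log <- function(path) {
  if (!file.exists(path)) {
    abort_wm(sprintf("no raw log at '%s'", path), "wm_io_error")
  }
  lines <- readr::read_lines(path)
  body <- lines[-1]
  parsed <- parse_log_lines(body, start_no = 2L)
  if (nrow(parsed$bad) > 0) {
    rlang::warn(sprintf("raw log: %d malformed line(s) skipped (line %s)",
                        nrow(parsed$bad),
                        paste(parsed$bad$line, collapse = ", ")))
    return(structure(parsed$lines, bad_lines = parsed$bad))
  }
  parsed$lines
}

#' Per-patient report
#'
#' Recomputes the processed view of a patient's training from the raw log:
#' one row per executed block (date/time, exercise, parameter snapshot,
#' correct/incorrect/missed counts, difficulty level) plus the maximum
#' difficulty level achieved per exercise type.
#'
#' @param store A [wm_store()] whose raw log holds the patient's blocks.
#' @param patient_id Patient to report on (must exist in the store).
#' @return A `wm_report`: list with `patient_id`, `blocks` tibble and
#'   `max_levels` tibble.
#' @export
generate_report <- function(store, patient_id) {
  stopifnot(inherits(store, "wm_store"))
  if (!patient_id %in% store$patients$patient_id) {
    abort_wm(sprintf("unknown patient '%s'", patient_id), "wm_lookup_error")
  }
  blocks <- if (file.exists(store$log_path)) {
    log <- read_raw_log(store$log_path)
    log[log$patient_id == patient_id, , drop = FALSE]
  } else {
    parse_log_lines(character(), 2L)$lines
  }
  max_levels <- if (nrow(blocks) > 0) {
    blocks |>
      dplyr::group_by(.data$exercise_type) |>
      dplyr::summarise(max_level = max(.data$level), .groups = "drop")
  } else {
    tibble::tibble(exercise_type = character(), max_level = integer())
  }
  structure(list(patient_id = patient_id,
                 blocks = tibble::as_tibble(blocks),
                 max_levels = max_levels),
            class = "wm_report")
}

#' @export
print.wm_report <- function(x, ...) {
  cat(sprintf("<wm_report: patient %s, %d blocks>\n",
              x$patient_id, nrow(x$blocks)))
  if (nrow(x$max_levels) > 0) {
    cat("maximum level achieved:\n")
    print(x$max_levels)
  }
  invisible(x)
}

#' Write a report to disk
#'
#' @param report A `wm_report`.
#' @param path Destination TSV for the per-block table.
#' @param text_path Optional human-readable text summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, text_path = NULL) {
  stopifnot(inherits(report, "wm_report"))
  readr::write_tsv(report$blocks, path)
  if (!is.null(text_path)) {
    lines <- c(sprintf("Training report for patient %s", report$patient_id),
               sprintf("Blocks executed: %d", nrow(report$blocks)),
               if (nrow(report$max_levels) > 0) {
                 sprintf("Maximum level achieved (%s): %d",
                         report$max_levels$exercise_type,
                         report$max_levels$max_level)
               } else "No blocks executed.")
    readr::write_lines(lines, text_path)
  }
  invisible(path)
}

bundle_tables <- function() c("patients", "records", "assignments", "settings")

#' Export / import a store bundle
#'
#' `export_bundle()` writes the three store sections as TSV files plus the
#' raw log into `dest`, together with a `MANIFEST.tsv` of MD5 checksums.
#' `import_bundle()` verifies every checksum (a tampered or truncated file
#' raises an integrity error) and reconstructs an equivalent store; logs
#' round-trip bit-identically.
#'
#' @param store A [wm_store()].
#' @param dest Destination directory (created; must be empty or absent
#'   unless `overwrite`).
#' @param overwrite Replace an existing bundle?
#' @return `dest` invisibly; for `import_bundle()`, the reconstructed store.
#' @export
export_bundle <- function(store, dest, overwrite = FALSE) {
  stopifnot(inherits(store, "wm_store"))
  if (dir.exists(dest) && length(dir(dest)) > 0 && !overwrite) {
    abort_wm(sprintf("destination '%s' is not empty", dest), "wm_io_error")
  }
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (tab in bundle_tables()) {
    f <- file.path(dest, paste0(tab, ".tsv"))
    readr::write_tsv(store[[tab]], f, na = "NA")
    files <- c(files, f)
  }
  if (file.exists(store$log_path)) {
    f <- file.path(dest, "raw_log.tsv")
    file.copy(store$log_path, f, overwrite = TRUE)
    files <- c(files, f)
  }
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(dest, "MANIFEST.tsv"))
  invisible(dest)
}

#' @rdname export_bundle
#' @param src Directory written by `export_bundle()`.
#' @param dir Directory for the imported store's raw log.
#' @export
import_bundle <- function(src, dir = tempfile("wm_store_")) {
  manifest_path <- file.path(src, "MANIFEST.tsv")
  if (!file.exists(manifest_path)) {
    abort_wm(sprintf("'%s' is not a store bundle (no MANIFEST.tsv)", src),
             "wm_io_error")
  }
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(src, manifest$file[[i]])
    sum <- unname(tools::md5sum(f))
    if (is.na(sum) || sum != manifest$md5[[i]]) {
      abort_wm(sprintf("bundle integrity failure: '%s' is missing or modified",
                       manifest$file[[i]]), "wm_integrity_error")
    }
  }
  store <- wm_store(dir)
  col_types <- list(patients = "ccc", records = "cccilcc",
                    assignments = "cccil", settings = "lcc")
  for (tab in bundle_tables()) {
    f <- file.path(src, paste0(tab, ".tsv"))
    if (file.exists(f)) {
      store[[tab]] <- readr::read_tsv(f, col_types = col_types[[tab]],
                                      na = "NA")
    }
  }
  log <- file.path(src, "raw_log.tsv")
  if (file.exists(log)) file.copy(log, store$log_path, overwrite = TRUE)
  store
}
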