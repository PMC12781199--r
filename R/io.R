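#' CSV dialect options for C2 Xplore operation files
#'
#' The device exports one CSV file per operation, one row per evoked EMG
#' signal, 1410 fields per row: 10 metadata fields followed by 1400 waveform
#' samples (70 ms at 0.05 ms). German-locale exports with `;` delimiter and
#' decimal comma are common, so both marks are configurable.
#'
#' @param delimiter Field separator (default `","`).
#' @param decimal_mark Decimal mark used for numeric fields (default `"."`).
#' @param header Whether the file carries a header row (default `TRUE`).
#' @return A list of class `ionm_dialect`.
#' @export
ionm_dialect <- function(delimiter = ",", decimal_mark = ".", header = TRUE) {
  if (identical(delimiter, decimal_mark)) {
    abort("delimiter and decimal_mark must differ")
  }
  structure(
    list(delimiter = delimiter, decimal_mark = decimal_mark, header = header),
    class = "ionm_dialect"
  )
}

operation_columns <- function() {
  c(METADATA_FIELDS, sprintf("s%04d", seq_len(WAVEFORM_N)))
}

#' Read a per-operation IONM CSV file
#'
#' Parses a C2 Xplore-dialect export into a tidy tibble: one row per EMG
#' signal with the 10 metadata fields as columns and the 1400-sample waveform
#' as a list-column. Rows are sorted by stimulation time. Records with empty
#' or non-standard labels are retained; use [filter_standard_labels()] to
#' keep only classification targets.
#'
#' @param path Path to the CSV file.
#' @param dialect An [ionm_dialect()] describing the file's format.
#' @param operation_id Identifier for the operation; defaults to the file
#'   name without extension.
#' @param modality `"cIONM"`, `"iIONM"` or `NA` when unknown (not stored in
#'   the device export).
#' @return A tibble with columns `operation_id`, `modality`, the 10 metadata
#'   fields and `waveform` (list of numeric vectors of length 1400). An empty
#'   file yields a zero-row tibble.
#' @export
read_operation_csv <- function(path, dialect = ionm_dialect(),
                               operation_id = NULL, modality = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  operation_id <- operation_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect$header && length(lines) > 0) lines <- lines[-1]
  if (length(lines) == 0) return(empty_operation_tibble(operation_id, modality))

  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 1410L)
  if (length(bad) > 0) {
    abort(sprintf(
      "row %d of %s has %d fields, expected 1410",
      bad[1] + as.integer(dialect$header), basename(path), nf[bad[1]]
    ))
  }
  m <- matrix(unlist(fields), nrow = length(fields), ncol = 1410L, byrow = TRUE)
  text_cols <- match(c("baseline_flag", "label"), METADATA_FIELDS)
  num_cols <- setdiff(seq_len(1410L), text_cols)
  numtxt <- m[, num_cols, drop = FALSE]
  if (!identical(dialect$decimal_mark, ".")) {
    numtxt[] <- gsub(dialect$decimal_mark, ".", numtxt, fixed = TRUE)
  }
  num <- suppressWarnings(array(as.numeric(numtxt), dim = dim(numtxt)))
  blank <- !nzchar(trimws(numtxt))
  if (any(is.na(num) & !blank)) {
    idx <- which(is.na(num) & !blank, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "row %d of %s: unparsable numeric field '%s'",
      idx[1] + as.integer(dialect$header), basename(path), numtxt[idx[1], idx[2]]
    ))
  }

  meta_num <- num[, 1:8, drop = FALSE]
  wave <- num[, 9:ncol(num), drop = FALSE]
  out <- tibble::tibble(
    operation_id = operation_id,
    modality = modality,
    stimulation_time = meta_num[, 1],
    stimulation_current = meta_num[, 2],
    amplitude = meta_num[, 3],
    onset_latency = meta_num[, 4],
    min_peak_latency = meta_num[, 5],
    max_peak_latency = meta_num[, 6],
    stimulating_channel = as.integer(meta_num[, 7]),
    recording_channel = as.integer(meta_num[, 8]),
    baseline_flag = m[, text_cols[1]],
    label = m[, text_cols[2]],
    waveform = lapply(seq_len(nrow(wave)), function(i) wave[i, ])
  )
  validate_operation_records(out)
  dplyr::arrange(out, .data$stimulation_time)
}

empty_operation_tibble <- function(operation_id = NULL, modality = NULL) {
  tibble::tibble(
    operation_id = character(), modality = character(),
    stimulation_time = numeric(), stimulation_current = numeric(),
    amplitude = numeric(), onset_latency = numeric(),
    min_peak_latency = numeric(), max_peak_latency = numeric(),
    stimulating_channel = integer(), recording_channel = integer(),
    baseline_flag = character(), label = character(),
    waveform = list()
  )
}

validate_operation_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  len <- lengths(records$waveform)
  if (any(len != WAVEFORM_N)) {
    abort(sprintf(
      "waveform length must be %d (record %d has %d samples)",
      WAVEFORM_N, which(len != WAVEFORM_N)[1], len[len != WAVEFORM_N][1]
    ))
  }
  if (!all(records$stimulating_channel %in% c(1L, 2L))) {
    abort("stimulating_channel must be 1 or 2")
  }
  if (!all(records$recording_channel %in% 1:4)) {
    abort("recording_channel must be in 1..4")
  }
  if (any(records$stimulation_time < 0)) {
    abort("stimulation_time must be non-negative")
  }
  lat <- c(records$onset_latency, records$min_peak_latency,
           records$max_peak_latency)
  lat <- lat[!is.na(lat)]
  if (any(lat < 0 | lat > 70)) abort("latencies must lie in [0, 70] ms")
  invisible(records)
}

#' Write records back to the C2 Xplore CSV dialect
#'
#' Serializes each record as one row of exactly 1410 fields in the documented
#' column order (10 metadata fields, then 1400 waveform samples). Numeric
#' fields are written with 15 significant digits so that a read/write
#' round-trip preserves values to better than 1e-9 relative.
#'
#' @param records A records tibble as produced by [read_operation_csv()] or
#'   [simulate_operation()]. Extra columns (e.g. `true_label`) are ignored.
#' @param path Output file path.
#' @param dialect An [ionm_dialect()].
#' @return `path`, invisibly.
#' @export
write_operation_csv <- function(records, path, dialect = ionm_dialect()) {
  validate_operation_records(records)
  fmt_num <- function(x) {
    out <- formatC(x, digits = 15, format = "g", flag = "")
    out <- trimws(out)
    out[is.na(x)] <- ""
    if (!identical(dialect$decimal_mark, ".")) {
      out <- gsub(".", dialect$decimal_mark, out, fixed = TRUE)
    }
    out
  }
  n <- nrow(records)
  header <- paste(operation_columns(), collapse = dialect$delimiter)
  if (n == 0) {
    readr::write_lines(if (dialect$header) header else character(), path)
    return(invisible(path))
  }
  meta <- cbind(
    fmt_num(records$stimulation_time), fmt_num(records$stimulation_current),
    fmt_num(records$amplitude), fmt_num(records$onset_latency),
    fmt_num(records$min_peak_latency), fmt_num(records$max_peak_latency),
    fmt_num(records$stimulating_channel), fmt_num(records$recording_channel),
    records$baseline_flag, records$label
  )
  wave <- matrix(fmt_num(unlist(records$waveform)),
                 nrow = n, ncol = WAVEFORM_N, byrow = TRUE)
  rows <- apply(cbind(meta, wave), 1, paste, collapse = dialect$delimiter)
  readr::write_lines(c(if (dialect$header) header, rows), path)
  invisible(path)
}

#' Keep only records carrying one of the 12 standard labels
#'
#' Annotation records ("baseline", "LOS", "artefact", ...) and records with
#' an empty label column document the course of surgery but are not
#' classification targets; this drops them while preserving record order.
#' The operation is idempotent.
#'
#' @param records A records tibble.
#' @param vocab A label vocabulary, see [ionm_label_vocabulary()].
#' @return The subset of `records` whose `label` is standard.
#' @export
filter_standard_labels <- function(records, vocab = ionm_label_vocabulary()) {
  dplyr::filter(records, .data$label %in% vocab$standard)
}

#' Duration of each operation in a records tibble
#'
#' @param records A records tibble (possibly several operations).
#' @return A tibble with `operation_id` and `duration` (ms, the largest
#'   stimulation time observed).
#' @export
operation_duration <- function(records) {
  records |>
    dplyr::group_by(.data$operation_id) |>
    dplyr::summarise(duration = max(.data$stimulation_time), .groups = "drop")
}

#' Write / read the simulator's ground-truth sidecar table
#'
#' The simulator returns ground truth (`true_label`, `label_error`) alongside
#' the stored label; these helpers persist it as a plain CSV keyed by record
#' index within the operation file.
#'
#' @param records A simulated records tibble.
#' @param path Sidecar CSV path.
#' @return `path` invisibly; `read_truth_csv()` returns a tibble.
#' @export
write_truth_csv <- function(records, path) {
  truth <- tibble::tibble(
    row = seq_len(nrow(records)),
    operation_id = records$operation_id,
    true_label = records[["true_label"]] %||% NA_character_,
    label_error = records[["label_error"]] %||% FALSE
  )
  readr::write_csv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
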