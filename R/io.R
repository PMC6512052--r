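#' Read an annotated ECG record
#'
#' Reads a record either in the plain-text fixture dialect written by
#' [write_record()] (`<stem>.csv` signal + `<stem>.json` sidecar) or in
#' WFDB form (`<stem>.hea` header, `<stem>.dat` format-212 signal,
#' `<stem>.atr` beat annotations). Signals are returned in physical units
#' (millivolts); for multi-lead WFDB records one channel is selected.
#'
#' @param path Path stem of the record (with or without extension).
#' @param dialect `"fixture"` or `"wfdb"`.
#' @param channel For WFDB records with several leads, which lead to read
#'   (1-based). Defaults to the first.
#' @return An [ecg_record()].
#' @export
#' @seealso [write_record()], [symbol_to_class()]
read_record <- function(path, dialect = c("fixture", "wfdb"), channel = 1L) {
  dialect <- match.arg(dialect)
  path <- sub("\\.(csv|json|hea|dat|atr)$", "", path)
  switch(dialect,
         fixture = read_record_fixture(path),
         wfdb = read_record_wfdb(path, channel = channel))
}

#' Write an annotated ECG record in the fixture dialect
#'
#' Writes `<stem>.csv` holding the signal as a single `amplitude` column of
#' decimal millivolts, and `<stem>.json` holding `record_id`, `fs` and the
#' annotation list. Values are formatted with enough digits that
#' [read_record()] inverts the write bit-exactly.
#'
#' @param record An [ecg_record()].
#' @param path Path stem to write to (directory must exist).
#' @param dialect Only `"fixture"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, dialect = "fixture") {
  stopifnot(inherits(record, "ecg_record"))
  dialect <- match.arg(dialect, "fixture")
  path <- sub("\\.(csv|json)$", "", path)
  con <- file(paste0(path, ".csv"), open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("amplitude", con)
  writeLines(sprintf("%.17g", record$signal), con)
  sidecar <- list(
    record_id = record$record_id,
    fs = record$fs,
    annotations = lapply(seq_len(nrow(record$annotations)), function(i) {
      list(sample = record$annotations$sample[i],
           symbol = record$annotations$symbol[i])
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_record_fixture <- function(path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  for (f in c(csv, json)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  lines <- readLines(csv)
  if (length(lines) == 0 || lines[1] != "amplitude") {
    abort(sprintf("%s: expected a single 'amplitude' CSV column", csv))
  }
  signal <- as.double(lines[-1])
  if (anyNA(signal)) abort(sprintf("%s: non-numeric amplitude values", csv))
  meta <- jsonlite::read_json(json)
  ann <- tibble::tibble(
    sample = vapply(meta$annotations, function(a) as.integer(a$sample), 1L),
    symbol = vapply(meta$annotations, function(a) as.character(a$symbol), "")
  )
  ecg_record(meta$record_id, signal, as.double(meta$fs), ann)
}

#' Standard paced-record identifiers
#'
#' The four MIT-BIH arrhythmia records acquired from patients with pacemakers,
#' conventionally excluded from beat-classification experiments. The set is a
#' default, not a constraint: dataset-assembly functions accept any exclusion
#' list.
#'
#' @return Character vector of record IDs.
#' @export
paced_record_ids <- function() {
  c("102", "104", "107", "217")
}
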