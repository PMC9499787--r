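# Reading/writing pulse recordings and dataset manifests, plus the
# initial-pressure baseline subtraction. On disk a record is a headerless
# two-column text file (time in seconds, pressure in Pa); an optional JSON
# sidecar carries the label, nominal sampling rate, seed and ground-truth
# fiducial indices.

validate_record <- function(record, source = "record") {
  if (nrow(record) < 2) {
    abort_pulsekit(sprintf("%s: a pulse record needs at least 2 samples.", source),
      "pulsekit_empty_record")
  }
  if (is.unsorted(record$time, strictly = TRUE)) {
    abort_pulsekit(sprintf("%s: timestamps must be strictly increasing.", source),
      "pulsekit_nonmonotone_time")
  }
  invisible(record)
}

#' Read a pulse record from a delimited text file
#'
#' Expects two numeric columns, time (s) then pressure (Pa), without a
#' header. Rows containing non-finite values are dropped with a message.
#' Use `swap_columns = TRUE` for files written pressure-first.
#'
#' @param path File path (CSV or TSV; the delimiter is sniffed).
#' @param swap_columns Set `TRUE` when the file stores (pressure, time).
#' @param label Optional Mai class label to attach.
#' @param fs Optional nominal sampling rate; inferred from the median
#'   timestamp spacing when absent.
#' @param source_id Identifier stored on the record (defaults to the file name).
#' @return A `pulse_record` tibble.
#' @export
read_pulse <- function(path, swap_columns = FALSE, label = NULL, fs = NULL,
                       source_id = basename(path)) {
  if (!file.exists(path)) {
    abort_pulsekit(sprintf("File not found: %s", path), "pulsekit_missing_file")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    abort_pulsekit(sprintf("%s: empty file.", path), "pulsekit_empty_record")
  }
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_names = FALSE, trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 2) {
    abort_pulsekit(sprintf("%s: need two numeric columns (time, pressure).", path),
      "pulsekit_bad_columns")
  }
  raw <- raw[, 1:2]
  names(raw) <- if (swap_columns) c("pressure", "time") else c("time", "pressure")
  ok <- is.finite(raw$time) & is.finite(raw$pressure)
  if (any(!ok)) {
    inform(sprintf("%s: dropped %d row(s) with non-finite values.", path, sum(!ok)))
    raw <- raw[ok, ]
  }
  if (nrow(raw) < 2) {
    abort_pulsekit(sprintf("%s: a pulse record needs at least 2 samples.", path),
      "pulsekit_empty_record")
  }
  rec <- new_pulse_record(raw$time, raw$pressure,
    label = label,
    fs_nominal = fs %||% infer_fs(raw$time), source_id = source_id
  )
  validate_record(rec, path)
  rec
}

#' Write a pulse record to disk
#'
#' Writes a headerless two-column CSV (time, pressure) at full double
#' precision (15 significant digits, so read-back reproduces the record),
#' plus an optional JSON sidecar with label, nominal rate, and ground-truth
#' fiducials when present.
#'
#' @param record A `pulse_record`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` metadata (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_pulse <- function(record, path, sidecar = TRUE) {
  validate_record(record, "record")
  lines <- paste(
    sprintf("%.15g", record$time),
    sprintf("%.15g", record$pressure),
    sep = ","
  )
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(
      label = attr(record, "label"),
      fs = attr(record, "fs"),
      source_id = attr(record, "source_id"),
      ground_truth = ground_truth(record)
    )
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Write and read a dataset manifest
#'
#' A manifest is a JSON array of `{file, label, fs}` entries mapping record
#' files to class labels.
#'
#' @param dataset A tibble with `source_id`, `label`, `record` columns, as
#'   returned by [make_dataset()].
#' @param dir Directory to write records and the manifest into.
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- purrr::pmap(dataset, function(source_id, label, record) {
    file <- file.path(dir, paste0(source_id, ".csv"))
    write_pulse(record, file)
    list(file = basename(file), label = label, fs = attr(record, "fs"))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param manifest Path to a `manifest.json`.
#' @export
read_dataset <- function(manifest) {
  entries <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  purrr::map_dfr(entries, function(e) {
    rec <- read_pulse(file.path(dir, e$file), label = e$label, fs = e$fs)
    tibble(source_id = sub("\\.csv$", "", e$file), label = e$label, record = list(rec))
  })
}

#' Subtract the initial-pressure baseline
#'
#' Pressure sensors carry an initial offset that must be removed before
#' analysis. With a numeric `baseline` the pressure is shifted by that
#' amount; with `"auto"` the minimum over the first beat-length window
#' (default 1.5 s, enough to contain one onset valley at any physiological
#' rate) is used.
#'
#' @param record A `pulse_record` (or any data frame with `time`/`pressure`).
#' @param baseline Numeric offset in Pa, or `"auto"`.
#' @param window_s Window (s) over which `"auto"` takes the minimum.
#' @return The record with shifted pressure; the offset used is stored in
#'   the `baseline` attribute.
#' @export
#' @examples
#' rec <- synthesize_record(make_template("Pingmai"), 4, noise = zero_noise())
#' min(subtract_baseline(rec)$pressure)
subtract_baseline <- function(record, baseline = "auto", window_s = 1.5) {
  validate_record(record)
  if (identical(baseline, "auto")) {
    w <- record$time <= record$time[1] + window_s
    baseline <- min(record$pressure[w])
  }
  assert_scalar_number(baseline, "baseline")
  out <- record
  out$pressure <- record$pressure - baseline
  attr(out, "baseline") <- baseline
  out
}
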