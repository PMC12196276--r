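# On-disk formats: angle CSV (comma, dot decimal, header), signal CSV,
# event/feature TSV, report JSON. All readers validate; none guess at
# truncated or malformed input.

#' Write an ankle-angle trace to CSV
#'
#' Columns `time`, `dorsiflexion`, `inversion`; RFC-4180 dialect (comma
#' separator, dot decimal, header row) as produced by rotary-encoder ankle
#' goniometer systems.
#'
#' @param trace an [angle_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(trace, path) {
  stopifnot(inherits(trace, "angle_trace"))
  df <- data.frame(time = trace$time, dorsiflexion = trace$dorsiflexion,
                   inversion = trace$inversion)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ankle-angle trace from CSV
#'
#' The header must name `time`, `dorsiflexion` and `inversion` columns. The
#' sampling rate is inferred from the median time delta and checked against
#' `rate` within 1%.
#'
#' @param path CSV file path.
#' @param rate declared nominal sampling rate in Hz (default 50).
#' @return An [angle_trace()].
#' @export
read_angle_csv <- function(path, rate = 50) {
  if (!file.exists(path))
    stop_cmc("file not found: %s", path, class = "cmcgait_io_error")
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "dorsiflexion", "inversion")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop_cmc("angle CSV %s lacks column(s): %s", path,
             paste(missing_col, collapse = ", "), class = "cmcgait_schema_error")
  if (nrow(df) < 2)
    stop_cmc("angle CSV %s has fewer than 2 rows", path, class = "cmcgait_data_error")
  dt <- diff(df$time)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop_cmc("non-monotone time in %s at row %d", path, bad, class = "cmcgait_data_error")
  }
  inferred <- 1 / stats::median(dt)
  if (!is.null(rate) && abs(inferred - rate) / rate > 0.01)
    stop_cmc("inferred rate %.3f Hz differs from declared %g Hz by more than 1%%",
             inferred, rate, class = "cmcgait_data_error")
  angle_trace(df$time, df$dorsiflexion, df$inversion, rate = rate %||% inferred)
}

#' Write a signal record to CSV
#'
#' Wide layout: a `time` column followed by one column per channel (values in
#' microvolts).
#'
#' @param record a [signal_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  df <- data.frame(time = record$start_time + (seq_len(ncol(record$samples)) - 1L) / record$rate)
  for (ch in record$channels) df[[ch]] <- record$samples[ch, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multichannel signal file
#'
#' The canonical on-disk format is the wide CSV written by
#' [write_signal_csv()]. The reader validates that the required channels for
#' the requested analysis are present and that the sampling rate inferred
#' from the time column matches `rate` within 1%.
#'
#' @param path file path.
#' @param format `"csv"`. (`"edf"` is recognised but not supported by this
#'   package; an informative error is raised.)
#' @param rate declared sampling rate in Hz (default 1000).
#' @param required_channels channels that must be present (default
#'   `c("Cz", "TA")`; add `"EOG_up"`, `"EOG_down"` when EOG regression is
#'   enabled).
#' @param delimiter field separator, `","` by default.
#' @return A [signal_record()].
#' @export
read_signals <- function(path, format = c("csv", "edf"), rate = 1000,
                         required_channels = c("Cz", "TA"), delimiter = ",") {
  format <- match.arg(format)
  if (format == "edf")
    stop_cmc("EDF input is not supported; convert to the CSV layout of write_signal_csv()",
             class = "cmcgait_format_error")
  if (!file.exists(path))
    stop_cmc("file not found: %s", path, class = "cmcgait_io_error")
  df <- utils::read.csv(path, check.names = FALSE, sep = delimiter)
  if (!"time" %in% names(df) || ncol(df) < 2)
    stop_cmc("signal CSV %s: expected a 'time' column plus channel columns (is the delimiter '%s' right?)",
             path, delimiter, class = "cmcgait_parse_error")
  missing_ch <- setdiff(required_channels, names(df))
  if (length(missing_ch))
    stop_cmc("signal CSV %s lacks required channel(s): %s", path,
             paste(missing_ch, collapse = ", "), class = "cmcgait_channel_error")
  dt <- diff(df$time)
  if (any(dt <= 0))
    stop_cmc("non-monotone time in %s", path, class = "cmcgait_data_error")
  inferred <- 1 / stats::median(dt)
  if (!is.null(rate) && abs(inferred - rate) / rate > 0.01)
    stop_cmc("inferred rate %.3f Hz differs from declared %g Hz", inferred, rate,
             class = "cmcgait_config_error")
  channels <- setdiff(names(df), "time")
  samples <- t(as.matrix(df[channels]))
  signal_record(samples, channels, rate = rate %||% inferred, start_time = df$time[1L])
}

#' Write / read event tables as TSV
#'
#' One row per event with columns `label`, `time`, `trial`.
#'
#' @param events an [event_table()].
#' @param path file path.
#' @return `path` (writer) or an [event_table()] (reader).
#' @export
write_event_tsv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path) {
  if (!file.exists(path))
    stop_cmc("file not found: %s", path, class = "cmcgait_io_error")
  df <- utils::read.delim(path)
  need <- c("label", "time", "trial")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop_cmc("event TSV %s lacks column(s): %s", path,
             paste(missing_col, collapse = ", "), class = "cmcgait_schema_error")
  event_table(df$label, df$time, df$trial)
}

#' Write / read subject-by-window feature tables as TSV
#'
#' Long layout with columns `subject`, `window`, `value`, `group`. An empty
#' table writes a header-only file.
#'
#' @param table data.frame with columns `subject`, `window`, `value`, `group`.
#' @param path file path.
#' @return `path` (writer) or the table (reader).
#' @export
write_feature_tsv <- function(table, path) {
  need <- c("subject", "window", "value", "group")
  missing_col <- setdiff(need, names(table))
  if (length(missing_col))
    stop_cmc("feature table lacks column(s): %s", paste(missing_col, collapse = ", "),
             class = "cmcgait_schema_error")
  utils::write.table(table[need], path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  if (!file.exists(path))
    stop_cmc("file not found: %s", path, class = "cmcgait_io_error")
  df <- utils::read.delim(path, colClasses = c(subject = "character", window = "character",
                                               value = "numeric", group = "character"))
  need <- c("subject", "window", "value", "group")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop_cmc("feature TSV %s lacks column(s): %s", path,
             paste(missing_col, collapse = ", "), class = "cmcgait_schema_error")
  df
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write an analysis report as JSON
#'
#' Reports (group statistics, classifier metrics, run manifests) are written
#' as JSON with a `schema_version` field so downstream consumers can detect
#' layout changes.
#'
#' @param report a named list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(is.list(report))
  report$schema_version <- REPORT_SCHEMA_VERSION
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  if (!file.exists(path))
    stop_cmc("file not found: %s", path, class = "cmcgait_io_error")
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema_version))
    stop_cmc("report %s lacks schema_version", path, class = "cmcgait_schema_error")
  rep
}
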