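#' Multichannel biosignal record
#'
#' Container for one subject's raw or preprocessed time series (EEG, EMG and
#' optionally EOG channels) sampled at a common rate. Samples are stored as a
#' channel-by-time matrix in microvolts.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param channels character vector of unique channel labels, one per row.
#' @param rate sampling rate in Hz (> 0).
#' @param start_time recording start time in seconds (default 0).
#' @return An object of class `signal_record`.
#' @examples
#' rec <- signal_record(matrix(rnorm(2000), nrow = 2),
#'                      channels = c("Cz", "TA"), rate = 1000)
#' rec
#' @export
signal_record <- function(samples, channels, rate, start_time = 0) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_cmc("`samples` must be a numeric channel x time matrix", class = "cmcgait_type_error")
  if (length(channels) != nrow(samples))
    stop_cmc("%d channel labels for %d rows", length(channels), nrow(samples),
             class = "cmcgait_type_error")
  if (anyDuplicated(channels))
    stop_cmc("channel labels must be unique", class = "cmcgait_type_error")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_cmc("`rate` must be a single positive number", class = "cmcgait_type_error")
  rownames(samples) <- channels
  structure(list(samples = samples, channels = as.character(channels),
                 rate = rate, start_time = start_time),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, ncol(x$samples) / x$rate))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.signal_record` <- function(x, channels) {
  missing_ch <- setdiff(channels, x$channels)
  if (length(missing_ch))
    stop_cmc("channel(s) not present: %s", paste(missing_ch, collapse = ", "),
             class = "cmcgait_channel_error")
  signal_record(x$samples[channels, , drop = FALSE], channels, x$rate, x$start_time)
}

#' Two-plane ankle-angle trace
#'
#' Ankle joint angles in the sagittal (dorsiflexion/plantarflexion,
#' dorsiflexion positive) and frontal (inversion/eversion, inversion positive)
#' planes, sampled on a strictly increasing time axis (default 50 Hz, the
#' rate of rotary-encoder goniometer systems).
#'
#' @param time time stamps in seconds, strictly increasing.
#' @param dorsiflexion sagittal-plane angle in degrees.
#' @param inversion frontal-plane angle in degrees.
#' @param rate nominal sampling rate in Hz (default 50).
#' @return An object of class `angle_trace`.
#' @export
angle_trace <- function(time, dorsiflexion, inversion, rate = 50) {
  n <- length(time)
  if (length(dorsiflexion) != n || length(inversion) != n)
    stop_cmc("time/dorsiflexion/inversion lengths differ", class = "cmcgait_type_error")
  if (n >= 2 && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop_cmc("time axis not strictly increasing at row %d", bad,
             class = "cmcgait_data_error")
  }
  structure(list(time = as.numeric(time), dorsiflexion = as.numeric(dorsiflexion),
                 inversion = as.numeric(inversion), rate = rate),
            class = "angle_trace")
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("<angle_trace> %d samples @ %g Hz, t = [%.2f, %.2f] s\n",
              length(x$time), x$rate, x$time[1L], x$time[length(x$time)]))
  invisible(x)
}

#' Event table (movement onsets and gait events)
#'
#' @param label event labels, each one of `"onset"`, `"IC"` (initial contact)
#'   or `"TO"` (toe-off).
#' @param time event times in seconds, non-decreasing within a trial.
#' @param trial trial (or gait-pass) index.
#' @return A `data.frame` of class `event_table` with columns
#'   `label`, `time`, `trial`.
#' @export
event_table <- function(label, time, trial = 1L) {
  label <- as.character(label)
  bad <- setdiff(unique(label), c("onset", "IC", "TO"))
  if (length(bad))
    stop_cmc("unknown event label(s): %s", paste(bad, collapse = ", "),
             class = "cmcgait_type_error")
  df <- data.frame(label = label, time = as.numeric(time),
                   trial = as.integer(trial))
  for (tr in unique(df$trial)) {
    tt <- df$time[df$trial == tr]
    if (is.unsorted(tt))
      stop_cmc("event times decrease within trial %d", tr, class = "cmcgait_data_error")
  }
  class(df) <- c("event_table", "data.frame")
  df
}
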