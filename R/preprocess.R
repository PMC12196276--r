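# Preprocessing: zero-phase filtering, full-wave rectification, EOG
# regression, movement-onset detection and epoching.

butter_filtfilt <- function(x, filt) as.numeric(signal::filtfilt(filt, x))

#' Zero-phase filtering of a signal record
#'
#' Applies 4th-order Butterworth filters forward and backward
#' (`signal::filtfilt`), so filtering adds no phase delay and epoch timing is
#' preserved. Three canned filter kinds cover the pipeline:
#' \describe{
#'   \item{`notch60`}{band-stop around the mains frequency (default 60 Hz,
#'     bandwidth 2 Hz, i.e. 59--61 Hz).}
#'   \item{`emg_band`}{5--300 Hz band-pass for surface EMG.}
#'   \item{`eeg_band`}{0.5--45 Hz band-pass for EEG.}
#' }
#' Band-passes are applied as a high-pass/low-pass cascade, which is
#' numerically safer than a single transfer function when the lower edge is a
#' tiny fraction of the Nyquist frequency.
#'
#' @param record a [signal_record()].
#' @param kind one of `"notch60"`, `"emg_band"`, `"eeg_band"`.
#' @param channels channels to filter (default: all).
#' @param mains_hz mains frequency for the notch (default 60).
#' @param order Butterworth order per section (default 4; the notch uses 2).
#' @return A filtered [signal_record()] of the same shape and rate.
#' @export
filter_signal <- function(record, kind = c("notch60", "emg_band", "eeg_band"),
                          channels = NULL, mains_hz = 60, order = 4) {
  stopifnot(inherits(record, "signal_record"))
  kind <- match.arg(kind)
  nyq <- record$rate / 2
  channels <- channels %||% record$channels
  missing_ch <- setdiff(channels, record$channels)
  if (length(missing_ch))
    stop_cmc("unknown channel(s): %s", paste(missing_ch, collapse = ", "),
             class = "cmcgait_channel_error")
  band <- switch(kind,
                 notch60 = c(mains_hz - 1, mains_hz + 1),
                 emg_band = c(5, 300),
                 eeg_band = c(0.5, 45))
  if (band[2] >= nyq)
    stop_cmc("cutoff %g Hz >= Nyquist %g Hz", band[2], nyq, class = "cmcgait_parameter_error")
  filts <- if (kind == "notch60") {
    list(signal::butter(2, band / nyq, type = "stop"))
  } else {
    list(signal::butter(order, band[1] / nyq, type = "high"),
         signal::butter(order, band[2] / nyq, type = "low"))
  }
  out <- record
  for (ch in channels) {
    x <- record$samples[ch, ]
    for (f in filts) x <- butter_filtfilt(x, f)
    out$samples[ch, ] <- x
  }
  out
}

#' Full-wave rectification
#'
#' Replaces the selected channels (typically the EMG channels, after
#' band-pass filtering) by their absolute value; other channels are untouched.
#'
#' @param record a [signal_record()].
#' @param channels channels to rectify (default `c("TA", "MG")` intersected
#'   with the available channels).
#' @return A [signal_record()].
#' @export
rectify <- function(record, channels = intersect(c("TA", "MG"), record$channels)) {
  stopifnot(inherits(record, "signal_record"))
  missing_ch <- setdiff(channels, record$channels)
  if (length(missing_ch))
    stop_cmc("unknown channel(s): %s", paste(missing_ch, collapse = ", "),
             class = "cmcgait_channel_error")
  record$samples[channels, ] <- abs(record$samples[channels, , drop = FALSE])
  record
}

#' Remove ocular artifacts by EOG regression
#'
#' Each EEG channel is replaced by its residual after least-squares
#' regression on the EOG channel pair (plus an intercept). EMG channels are
#' left untouched. This is the standard linear-regression form of EOG
#' artifact removal.
#'
#' @param record a [signal_record()].
#' @param eog_channels the EOG channel labels (default
#'   `c("EOG_up", "EOG_down")`).
#' @param eeg_channels channels to clean (default: all channels that are
#'   neither EOG nor the EMG channels `TA`/`MG`).
#' @param enabled if `FALSE`, the record is passed through unchanged.
#' @return A [signal_record()].
#' @export
regress_eog <- function(record, eog_channels = c("EOG_up", "EOG_down"),
                        eeg_channels = NULL, enabled = TRUE) {
  stopifnot(inherits(record, "signal_record"))
  if (!enabled) return(record)
  missing_ch <- setdiff(eog_channels, record$channels)
  if (length(missing_ch))
    stop_cmc("EOG channel(s) missing: %s", paste(missing_ch, collapse = ", "),
             class = "cmcgait_channel_error")
  eeg_channels <- eeg_channels %||%
    setdiff(record$channels, c(eog_channels, "TA", "MG"))
  X <- cbind(1, t(record$samples[eog_channels, , drop = FALSE]))
  # Guard all-zero EOG: qr handles rank deficiency; residual = original signal
  qrX <- qr(X)
  for (ch in eeg_channels) {
    y <- record$samples[ch, ]
    record$samples[ch, ] <- qr.resid(qrX, y) + mean(y)
  }
  record
}

#' Detect movement onsets from an ankle-angle trace
#'
#' An onset is the first sample at which the dorsiflexion angle exceeds its
#' local pre-movement baseline (median of the preceding `baseline_s` seconds)
#' by `threshold_deg` and stays above it for at least `min_hold_s`.
#' Successive onsets must be at least `min_separation_s` apart.
#'
#' @param trace an [angle_trace()].
#' @param threshold_deg threshold above baseline in degrees (default 2).
#' @param min_hold_s minimum supra-threshold hold in seconds (default 0.1).
#' @param baseline_s length of the preceding baseline window in seconds
#'   (default 1).
#' @param min_separation_s minimum spacing between onsets (default 5).
#' @return Numeric vector of onset times in seconds (possibly empty).
#' @export
detect_onset <- function(trace, threshold_deg = 2, min_hold_s = 0.1,
                         baseline_s = 1, min_separation_s = 5) {
  stopifnot(inherits(trace, "angle_trace"))
  if (threshold_deg <= 0)
    stop_cmc("threshold_deg must be > 0", class = "cmcgait_parameter_error")
  n <- length(trace$time)
  rate <- trace$rate
  if (n / rate <= min_hold_s)
    stop_cmc("trace shorter than min_hold_s", class = "cmcgait_parameter_error")
  wb <- max(2L, round(baseline_s * rate))
  d <- trace$dorsiflexion
  # right-aligned rolling median of the *preceding* window (exclude current)
  base <- c(rep(NA_real_, wb), zoo::rollapply(d, width = wb, FUN = stats::median,
                                              align = "right"))[seq_len(n)]
  above <- !is.na(base) & (d > base + threshold_deg)
  hold_n <- max(1L, round(min_hold_s * rate))
  onsets <- numeric(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < hold_n) next
    t_on <- trace$time[starts[k]]
    if (length(onsets) == 0 || t_on - onsets[length(onsets)] >= min_separation_s)
      onsets <- c(onsets, t_on)
  }
  onsets
}

#' Epoch a signal record around movement onsets
#'
#' Cuts `window` (default -3 to +3 s) around every onset without resampling:
#' samples inside an epoch are bit-identical to the source record. Onsets
#' whose window exceeds the recording are dropped with a warning; if no
#' usable trial remains an error is raised.
#'
#' @param record a [signal_record()].
#' @param onsets onset times in seconds.
#' @param window two-element window in seconds relative to onset
#'   (default `c(-3, 3)`).
#' @return An object of class `trial_epochs`: list with `data` (trial x
#'   channel x sample array), `time` (seconds relative to onset), `rate`,
#'   `channels`, `onsets`.
#' @export
epoch_trials <- function(record, onsets, window = c(-3, 3)) {
  stopifnot(inherits(record, "signal_record"), length(window) == 2L,
            window[1] < window[2])
  rate <- record$rate
  nsamp <- ncol(record$samples)
  wlen <- round((window[2] - window[1]) * rate)
  rel_time <- window[1] + (0:(wlen - 1L)) / rate
  keep <- logical(length(onsets))
  idx0 <- integer(length(onsets))
  for (i in seq_along(onsets)) {
    start <- round((onsets[i] - record$start_time + window[1]) * rate) + 1L
    if (start >= 1L && start + wlen - 1L <= nsamp) {
      keep[i] <- TRUE
      idx0[i] <- start
    }
  }
  if (any(!keep))
    warning(sprintf("dropped %d trial(s) whose window exceeds the recording",
                    sum(!keep)))
  if (!any(keep))
    stop_cmc("no usable trials after windowing", class = "cmcgait_epoching_error")
  onsets <- onsets[keep]
  idx0 <- idx0[keep]
  data <- array(NA_real_, dim = c(length(onsets), nrow(record$samples), wlen),
                dimnames = list(NULL, record$channels, NULL))
  for (i in seq_along(onsets))
    data[i, , ] <- record$samples[, idx0[i]:(idx0[i] + wlen - 1L)]
  structure(list(data = data, time = rel_time, rate = rate,
                 channels = record$channels, onsets = onsets),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  cat(sprintf("<trial_epochs> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
              x$time[1], x$time[length(x$time)] + 1 / x$rate))
  invisible(x)
}

#' Segment a trace or record into gait cycles
#'
#' A gait cycle spans two consecutive initial contacts (ICs) of the same
#' foot and must contain exactly one toe-off (TO); cycles without a TO are
#' dropped with a warning.
#'
#' @param x an [angle_trace()] or [signal_record()].
#' @param ic_times initial-contact times in seconds (>= 2 required).
#' @param to_times toe-off times in seconds.
#' @return List of cycles; each cycle is a list with `start`, `end`, `to`
#'   (times in seconds) and `trace`/`record`, the segment of `x` covering the
#'   cycle.
#' @export
epoch_gait <- function(x, ic_times, to_times) {
  if (length(ic_times) < 2)
    stop_cmc("need at least 2 IC events to form a gait cycle",
             class = "cmcgait_epoching_error")
  ic_times <- sort(ic_times)
  cycles <- list()
  dropped <- 0L
  for (k in seq_len(length(ic_times) - 1L)) {
    t0 <- ic_times[k]; t1 <- ic_times[k + 1L]
    to_in <- to_times[to_times > t0 & to_times < t1]
    if (length(to_in) != 1L) { dropped <- dropped + 1L; next }
    seg <- if (inherits(x, "angle_trace")) {
      sel <- x$time >= t0 & x$time <= t1
      angle_trace(x$time[sel], x$dorsiflexion[sel], x$inversion[sel], x$rate)
    } else if (inherits(x, "signal_record")) {
      tt <- x$start_time + (seq_len(ncol(x$samples)) - 1L) / x$rate
      sel <- tt >= t0 & tt <= t1
      signal_record(x$samples[, sel, drop = FALSE], x$channels, x$rate,
                    start_time = tt[sel][1L])
    } else stop_cmc("x must be an angle_trace or signal_record",
                    class = "cmcgait_type_error")
    cycles[[length(cycles) + 1L]] <- list(start = t0, end = t1, to = to_in,
                                          segment = seg)
  }
  if (dropped > 0L)
    warning(sprintf("dropped %d cycle(s) without a contained TO", dropped))
  if (length(cycles) == 0L)
    stop_cmc("no usable gait cycles", class = "cmcgait_epoching_error")
  cycles
}
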