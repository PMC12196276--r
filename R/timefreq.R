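# Time-frequency analysis: complex Morlet wavelet beta-band power at Cz,
# baseline normalization, and the 11-window motor-preparation features.

# Complex Morlet wavelet at frequency f with a fixed number of cycles.
# Normalized so that a unit-amplitude sinusoid at f yields |response|^2 = 1.
morlet_kernel <- function(f, rate, cycles = 7) {
  sd_t <- cycles / (2 * pi * f)
  half <- ceiling(3.5 * sd_t * rate)
  t <- (-half:half) / rate
  env <- exp(-t^2 / (2 * sd_t^2))
  w <- env * exp(2i * pi * f * t)
  w * (2 / sum(env))
}

#' Morlet wavelet power time courses
#'
#' Convolves the selected channel of each trial epoch with complex Morlet
#' wavelets (complex sinusoids under a Gaussian envelope, default 7 cycles)
#' and returns the squared magnitude, averaged over trials. Epochs are
#' reflection-padded for the convolution; samples within half a wavelet
#' length of the epoch edges are flagged.
#'
#' @param epochs a `trial_epochs` object from [epoch_trials()].
#' @param channel channel to analyse (default `"Cz"`).
#' @param freqs analysis frequencies in Hz (default 14:20, the beta band).
#' @param cycles wavelet width in cycles (default 7).
#' @return Object of class `beta_power_series`: list with `time` (s relative
#'   to onset), `power` (band power per sample: mean over `freqs` of the
#'   trial-averaged per-frequency power, in squared microvolts),
#'   `power_by_freq` (freq x sample matrix), `freqs`, `rate`, `edge_flag`
#'   (logical per sample), `n_trials`.
#' @export
morlet_power <- function(epochs, channel = "Cz", freqs = 14:20, cycles = 7) {
  stopifnot(inherits(epochs, "trial_epochs"))
  if (!channel %in% epochs$channels)
    stop_cmc("channel %s not in epochs", channel, class = "cmcgait_channel_error")
  nt <- dim(epochs$data)[1]
  ns <- dim(epochs$data)[3]
  kernels <- lapply(freqs, morlet_kernel, rate = epochs$rate, cycles = cycles)
  half_max <- max(vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1)))
  if (2L * half_max + 1L > ns)
    stop_cmc("widest wavelet (%d samples) longer than epoch (%d samples)",
             2L * half_max + 1L, ns, class = "cmcgait_parameter_error")
  pow <- matrix(0, nrow = length(freqs), ncol = ns)
  for (i in seq_len(nt)) {
    x <- epochs$data[i, channel, ]
    # reflection padding against convolution edge artifacts
    pad <- half_max
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(ns - pad):(ns - 1L)]))
    for (j in seq_along(freqs)) {
      resp <- conv_same(xp, kernels[[j]])[(pad + 1L):(pad + ns)]
      pow[j, ] <- pow[j, ] + Mod(resp)^2
    }
  }
  pow <- pow / nt
  edge <- seq_len(ns) <= half_max | seq_len(ns) > ns - half_max
  structure(list(time = epochs$time, power = colMeans(pow),
                 power_by_freq = pow, freqs = freqs, rate = epochs$rate,
                 edge_flag = edge, n_trials = nt, normalized = FALSE,
                 baseline_window = NULL, mode = NULL),
            class = "beta_power_series")
}

#' Baseline-normalize a beta-power series
#'
#' Expresses power relative to the mean over the pre-movement baseline
#' window (default -3.0 to -2.5 s): `percent` mode gives
#' `100 * (P - Pbase) / Pbase`, `absolute` mode gives `P - Pbase` (in squared
#' microvolts). Absolute mode is the default, matching group-mean
#' beta-power change values reported on the microvolt-squared scale.
#'
#' @param series a `beta_power_series` from [morlet_power()].
#' @param mode `"absolute"` (default) or `"percent"`.
#' @param baseline_window two-element window in seconds (default
#'   `c(-3, -2.5)`).
#' @return The series with `power` replaced by normalized power and
#'   `normalized = TRUE`.
#' @export
baseline_normalize <- function(series, mode = c("absolute", "percent"),
                               baseline_window = c(-3, -2.5)) {
  stopifnot(inherits(series, "beta_power_series"))
  mode <- match.arg(mode)
  sel <- series$time >= baseline_window[1] & series$time < baseline_window[2]
  if (!any(sel))
    stop_cmc("baseline window [%g, %g] s outside the epoch", baseline_window[1],
             baseline_window[2], class = "cmcgait_parameter_error")
  pbase <- mean(series$power[sel])
  if (mode == "percent" && pbase <= 0)
    stop_cmc("zero baseline power; percent normalization undefined",
             class = "cmcgait_normalization_error")
  series$power <- if (mode == "percent") 100 * (series$power - pbase) / pbase
                  else series$power - pbase
  series$normalized <- TRUE
  series$baseline_window <- baseline_window
  series$mode <- mode
  series$baseline_power <- pbase
  series
}

#' Crop a beta-power series to a time window
#'
#' Used to trim wavelet buffer margins: epochs can be cut wider than the
#' analysis window so that wavelet edge effects fall outside the retained
#' span, then cropped back.
#'
#' @param series a `beta_power_series`.
#' @param window two-element window in seconds.
#' @return The cropped series.
#' @export
crop_series <- function(series, window = c(-3, 3)) {
  stopifnot(inherits(series, "beta_power_series"))
  sel <- series$time >= window[1] - 1e-9 & series$time < window[2] - 1e-9
  if (!any(sel))
    stop_cmc("window [%g, %g] outside the series", window[1], window[2],
             class = "cmcgait_parameter_error")
  series$time <- series$time[sel]
  series$power <- series$power[sel]
  series$power_by_freq <- series$power_by_freq[, sel, drop = FALSE]
  series$edge_flag <- series$edge_flag[sel]
  series
}

#' Window boundaries of the motor-preparation/execution features
#'
#' Eleven contiguous 500 ms windows from -2500 ms to +3000 ms around
#' movement onset.
#'
#' @return data.frame with columns `window` (label), `start`, `end`
#'   (seconds).
#' @export
feature_windows <- function() {
  starts <- seq(-2.5, 2.5, by = 0.5)
  data.frame(window = sprintf("%d~%d ms", round(starts * 1000), round((starts + 0.5) * 1000)),
             start = starts, end = starts + 0.5)
}

#' Windowed beta-power features
#'
#' Means of the (normalized) beta-power series over the 11 half-open
#' windows `[start, end)` of [feature_windows()], ordered earliest to
#' latest. Windows touching edge-flagged samples carry a quality flag.
#'
#' @param series a `beta_power_series` (normally after
#'   [baseline_normalize()]).
#' @return data.frame of class `window_features`: columns `window`, `start`,
#'   `end`, `value`, `edge_contaminated`.
#' @export
window_features <- function(series) {
  stopifnot(inherits(series, "beta_power_series"))
  wins <- feature_windows()
  if (series$time[1] > min(wins$start) + 1e-9 ||
      series$time[length(series$time)] < max(wins$end) - 1e-9 - 1 / series$rate)
    stop_cmc("series does not span [%g, %g] s", min(wins$start), max(wins$end),
             class = "cmcgait_parameter_error")
  vals <- numeric(nrow(wins))
  edge <- logical(nrow(wins))
  for (k in seq_len(nrow(wins))) {
    sel <- series$time >= wins$start[k] - 1e-9 & series$time < wins$end[k] - 1e-9
    vals[k] <- mean(series$power[sel])
    edge[k] <- any(series$edge_flag[sel])
  }
  out <- cbind(wins, value = vals, edge_contaminated = edge)
  class(out) <- c("window_features", "data.frame")
  out
}
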