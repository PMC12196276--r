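# Biomechanical indicators from ankle-angle traces: dorsiflexion-task
# metrics and gait metrics. Angular velocity is reported in degrees/s from
# centered finite differences with a 5-sample running-median pre-smoothing
# (robust to encoder glitches; the median filter is the identity on smooth
# monotone segments, so noise-free peaks are recovered exactly).

angle_velocity <- function(x, rate, median_k = 5L) {
  if (median_k > 1L && length(x) > median_k)
    x <- stats::runmed(x, median_k, endrule = "keep")
  n <- length(x)
  v <- numeric(n)
  if (n >= 3L)
    v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * rate / 2
  if (n >= 2L) { v[1L] <- (x[2L] - x[1L]) * rate; v[n] <- (x[n] - x[n - 1L]) * rate }
  v
}

#' Dorsiflexion-task biomechanical metrics
#'
#' For each trial: angle change (maximum dorsiflexion within the extraction
#' window minus the angle at onset), peak dorsiflexion angular velocity and
#' peak inversion angular velocity (both in degrees/s, from centered
#' differences). The representative value is the mean over trials, never the
#' metric of the mean trace.
#'
#' @param trials list of per-trial [angle_trace()] segments whose time axis
#'   is relative to movement onset (onset at t = 0).
#' @param window_s extraction window after onset in seconds (default 3).
#' @param median_k running-median width for velocity pre-smoothing
#'   (default 5 samples).
#' @return Object of class `dorsiflexion_metrics`: list with `per_trial`
#'   (data.frame `angle_change`, `peak_dorsi_vel`, `peak_inv_vel`) and `mean`
#'   (named vector of trial means).
#' @export
dorsiflexion_metrics <- function(trials, window_s = 3, median_k = 5L) {
  if (window_s < 3)
    stop_cmc("extraction window must cover 3 s after onset", class = "cmcgait_parameter_error")
  rows <- lapply(trials, function(tr) {
    stopifnot(inherits(tr, "angle_trace"))
    if (max(tr$time) < window_s - 1e-9)
      stop_cmc("trial window shorter than %g s", window_s, class = "cmcgait_parameter_error")
    sel <- tr$time >= 0 & tr$time <= window_s + 1e-9
    i_on <- which.min(abs(tr$time))
    vd <- angle_velocity(tr$dorsiflexion, tr$rate, median_k)
    vi <- angle_velocity(tr$inversion, tr$rate, median_k)
    data.frame(angle_change = max(tr$dorsiflexion[sel]) - tr$dorsiflexion[i_on],
               peak_dorsi_vel = max(vd[sel]),
               peak_inv_vel = max(abs(vi[sel])))
  })
  per_trial <- do.call(rbind, rows)
  structure(list(per_trial = per_trial, mean = colMeans(per_trial)),
            class = "dorsiflexion_metrics")
}

#' Gait biomechanical metrics
#'
#' Per cycle: post-toe-off dorsiflexion change (maximum dorsiflexion within
#' the swing-initiation window, toe-off to toe-off + `post_to_frac` of the
#' cycle, minus the angle at toe-off) and the inversion angle at the initial
#' contact sample (nearest sample to the IC event). Gait speed is the pass
#' length divided by the traversal time, averaged over passes.
#'
#' @param cycles list of cycles as returned by [epoch_gait()] on an
#'   [angle_trace()].
#' @param post_to_frac fraction of the cycle after toe-off searched for the
#'   dorsiflexion maximum (default 0.2, the swing-initiation fifth).
#' @param pass_length_m walking-path length in meters (for speed).
#' @param pass_times_s traversal times per pass in seconds.
#' @return Object of class `gait_metrics`: list with `per_cycle` (data.frame
#'   `post_to_change`, `ic_inversion`), `speed_mps` and `mean`.
#' @export
gait_metrics <- function(cycles, post_to_frac = 0.2,
                         pass_length_m = NULL, pass_times_s = NULL) {
  rows <- lapply(cycles, function(cy) {
    tr <- cy$segment
    stopifnot(inherits(tr, "angle_trace"))
    dur <- cy$end - cy$start
    i_ic <- which.min(abs(tr$time - cy$start))
    i_to <- which.min(abs(tr$time - cy$to))
    sel <- tr$time >= cy$to & tr$time <= cy$to + post_to_frac * dur + 1e-9
    if (!any(sel)) return(NULL)
    data.frame(post_to_change = max(tr$dorsiflexion[sel]) - tr$dorsiflexion[i_to],
               ic_inversion = tr$inversion[i_ic])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop_cmc("no cycle yields gait metrics", class = "cmcgait_data_error")
  per_cycle <- do.call(rbind, rows)
  speed <- NA_real_
  if (!is.null(pass_length_m) && !is.null(pass_times_s)) {
    if (any(pass_times_s <= 0))
      stop_cmc("traversal times must be > 0", class = "cmcgait_data_error")
    speed <- mean(pass_length_m / pass_times_s)
  }
  structure(list(per_cycle = per_cycle,
                 speed_mps = speed,
                 mean = c(colMeans(per_cycle), speed_mps = speed)),
            class = "gait_metrics")
}
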