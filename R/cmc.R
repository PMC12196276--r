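# Corticomuscular coherence: segment-averaged magnitude-squared coherence,
# analytic confidence level, beta-band summary and median-split grouping.

#' Segment-averaged magnitude-squared coherence
#'
#' Estimates
#' \deqn{Coh_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f) \, P_{yy}(f))}
#' where the cross- and auto-spectra are averaged over N data segments (one
#' per trial by default: the 3 s movement-execution window of each of the 10
#' dorsiflexion trials, Hann-tapered, no overlap, giving a frequency
#' resolution of 1/3 Hz). Values are bounded in [0, 1]; 1 means a perfect
#' linear relation at that frequency, 0 independence.
#'
#' @param x,y numeric matrices of identical dimension, segments in rows
#'   (trials) and samples in columns, same sampling rate.
#' @param rate sampling rate in Hz.
#' @param alpha significance level for the attached confidence level
#'   (default 0.95).
#' @param taper `"hann"` (default) or `"none"`.
#' @return Object of class `coherence_spectrum`: list with `freq` (Hz),
#'   `msc`, `n_segments`, `alpha`, `confidence_level`.
#' @export
estimate_msc <- function(x, y, rate, alpha = 0.95, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (!all(dim(x) == dim(y)))
    stop_cmc("x and y must have identical segment layout", class = "cmcgait_parameter_error")
  N <- nrow(x); L <- ncol(x)
  if (N < 2)
    stop_cmc("need at least 2 segments", class = "cmcgait_parameter_error")
  w <- if (taper == "hann") hann_window(L) else rep(1, L)
  Pxy <- complex(real = numeric(L), imaginary = numeric(L))
  Pxx <- numeric(L); Pyy <- numeric(L)
  for (i in seq_len(N)) {
    xi <- x[i, ] - mean(x[i, ])
    yi <- y[i, ] - mean(y[i, ])
    if (all(xi == 0) || all(yi == 0))
      stop_cmc("zero-power segment in trial %d", i, class = "cmcgait_degenerate_segment_error")
    X <- stats::fft(xi * w); Y <- stats::fft(yi * w)
    Pxy <- Pxy + X * Conj(Y)
    Pxx <- Pxx + Mod(X)^2
    Pyy <- Pyy + Mod(Y)^2
  }
  nf <- floor(L / 2) + 1L
  freq <- (seq_len(nf) - 1L) * rate / L
  denom <- (Pxx * Pyy)[seq_len(nf)]
  msc <- ifelse(denom > 0, (Mod(Pxy)^2)[seq_len(nf)] / denom, NA_real_)
  msc <- pmin(pmax(msc, 0), 1)
  structure(list(freq = freq, msc = msc, n_segments = N, alpha = alpha,
                 confidence_level = confidence_level(N, alpha)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins, df = %.3g Hz, N = %d segments, CL(%.2f) = %.3f\n",
              length(x$freq), x$freq[2] - x$freq[1], x$n_segments, x$alpha,
              x$confidence_level))
  invisible(x)
}

#' Coherence confidence level
#'
#' The analytic threshold above which an N-segment coherence estimate is
#' significant at level `alpha` under the independence null:
#' \deqn{CL_\alpha = 1 - (1 - \alpha)^{1/(N-1)}}
#' It equals `alpha` at N = 2 and decreases monotonically to 0 as N grows.
#'
#' @param n_segments number of averaged segments (>= 2).
#' @param alpha significance level in (0, 1), default 0.95.
#' @return The confidence level, a value in (0, 1).
#' @export
confidence_level <- function(n_segments, alpha = 0.95) {
  if (any(n_segments < 2))
    stop_cmc("n_segments must be >= 2", class = "cmcgait_parameter_error")
  if (alpha <= 0 || alpha >= 1)
    stop_cmc("alpha must be in (0, 1)", class = "cmcgait_parameter_error")
  1 - (1 - alpha)^(1 / (n_segments - 1))
}

#' Band summary of a coherence spectrum
#'
#' Summarizes the magnitude-squared coherence over a frequency band (default
#' beta, 14--20 Hz) as the mean (default) or the peak over the band's bins,
#' and attaches significance against the spectrum's confidence level
#' (recomputed, never stored stale).
#'
#' @param spec a `coherence_spectrum`.
#' @param band two-element Hz interval (default `c(14, 20)`).
#' @param mode `"mean"` or `"peak"`.
#' @param subject optional subject identifier carried into the summary.
#' @param pair channel pair label (default `"Cz-TA"`).
#' @return Object of class `cmc_summary`: list with `subject`, `pair`,
#'   `band`, `value`, `mode`, `n_segments`, `alpha`, `confidence_level`,
#'   `significant`.
#' @export
band_summary <- function(spec, band = c(14, 20), mode = c("mean", "peak"),
                         subject = NA_character_, pair = "Cz-TA") {
  stopifnot(inherits(spec, "coherence_spectrum"))
  mode <- match.arg(mode)
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel))
    stop_cmc("band [%g, %g] Hz contains no frequency bins", band[1], band[2],
             class = "cmcgait_parameter_error")
  value <- if (mode == "mean") mean(spec$msc[sel]) else max(spec$msc[sel])
  cl <- confidence_level(spec$n_segments, spec$alpha)
  structure(list(subject = subject, pair = pair, band = band, value = value,
                 mode = mode, n_segments = spec$n_segments, alpha = spec$alpha,
                 confidence_level = cl, significant = value > cl),
            class = "cmc_summary")
}

#' Median split of per-subject coherence summaries
#'
#' Subjects at or above the cohort median are labelled `"high"`, the rest
#' `"low"`. With an odd cohort of distinct values this yields a high group
#' one larger than the low group (e.g. 12/11 for 23 subjects). Ties exactly
#' at the median are assigned high and reported via a message.
#'
#' @param values numeric vector of per-subject band coherence values, or a
#'   list of `cmc_summary` objects.
#' @return factor with levels `c("high", "low")`, plus attributes `median`.
#' @export
median_split <- function(values) {
  if (is.list(values) && all(vapply(values, inherits, logical(1), "cmc_summary")))
    values <- vapply(values, function(s) s$value, numeric(1))
  if (length(values) < 4)
    stop_cmc("need at least 4 subjects for a median split", class = "cmcgait_parameter_error")
  if (length(unique(values)) == 1L)
    stop_cmc("all coherence values identical; median split undefined",
             class = "cmcgait_degenerate_split_error")
  med <- stats::median(values)
  n_tie <- sum(values == med)
  if (n_tie > 0 && length(values) %% 2 == 0)
    message(sprintf("%d value(s) tie the median; assigned to the high group", n_tie))
  labels <- factor(ifelse(values >= med, "high", "low"), levels = c("high", "low"))
  attr(labels, "median") <- med
  labels
}
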