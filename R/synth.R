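# Synthetic-cohort generator. Emulates a 23-subject ankle-dorsiflexion /
# gait study: coupled Cz-TA beta-band activity with a planted coherence per
# subject, a planted event-related beta-power time course at Cz, planted
# biomechanical metrics, and gait traces with IC/TO events. All randomness
# flows from a single seed through named substreams, so identical configs
# give bit-identical cohorts.

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the structure of a 23-subject study: 12 high- and 11
#' low-coherence subjects, 10 dorsiflexion trials of 3 s movement / 7 s
#' rest, EEG/EMG at 1000 Hz, ankle angles at 50 Hz, beta band 14-20 Hz,
#' group Cz-TA beta coherence 0.28 +/- 0.02 vs 0.23 +/- 0.02 (on the
#' 10-segment estimated scale), -500--0 ms baseline-subtracted beta-power
#' features -0.40 +/- 0.24 vs 1.03 +/- 0.93 microvolt^2, and the
#' biomechanical group distributions listed in `biomech_params`. Angular
#' velocities are planted in degrees/s at one hundredth of the
#' corresponding published device readouts (see the package vignette for
#' the unit discussion); effect sizes are scale-invariant so group
#' statistics are unaffected.
#'
#' With `empirical = TRUE` (default) each group's draws are standardized so
#' the cohort reproduces the configured group means and SDs exactly, i.e.
#' the generator emulates the study whose summary statistics are fixed;
#' `empirical = FALSE` draws i.i.d. from the group Gaussians.
#'
#' @param n_high,n_low group sizes (default 12 / 11).
#' @param target_cmc_high,target_cmc_low group mean Cz-TA beta coherence in
#'   [0, 1], on the N-segment estimated scale (defaults 0.28 / 0.23).
#' @param cmc_sd between-subject SD of planted coherence (default 0.02).
#' @param erd_mean_high,erd_sd_high,erd_mean_low,erd_sd_low -500--0 ms
#'   baseline-subtracted beta-power feature distribution per group
#'   (microvolt^2).
#' @param erd2_mean_high,erd2_sd_high,erd2_mean_low,erd2_sd_low same for
#'   the 500--1000 ms window.
#' @param trial_count dorsiflexion trials per subject (default 10).
#' @param movement_s,rest_s movement and rest durations in seconds (3 / 7).
#' @param fs_eeg_emg,fs_angle sampling rates in Hz (1000 / 50).
#' @param beta_band beta band in Hz (default `c(14, 20)`).
#' @param baseline_power baseline Cz beta power in microvolt^2 (default 2,
#'   so a -0.4 change is a 20% desynchronization).
#' @param bg_sd broadband EEG background SD in microvolts (default 2).
#' @param blink_gain EOG-to-Cz mixing gain (default 0.05).
#' @param emg_mod_depth depth of the beta-drive amplitude modulation of the
#'   EMG carrier (default 0.3).
#' @param angle_noise_sd encoder noise SD in degrees (default 0.05; set 0
#'   for noise-free traces).
#' @param biomech_params named list of per-group `c(high_mean, high_sd,
#'   low_mean, low_sd)` vectors for `angle_change`, `peak_dorsi_vel`,
#'   `peak_inv_vel` (dorsiflexion task), `post_to_change`, `ic_inversion`,
#'   `gait_speed` (walking task).
#' @param empirical standardize group draws to exact moments (default TRUE).
#' @param seed integer master seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_high = 12, n_low = 11,
                         target_cmc_high = 0.28, target_cmc_low = 0.23,
                         cmc_sd = 0.02,
                         erd_mean_high = -0.40, erd_sd_high = 0.24,
                         erd_mean_low = 1.03, erd_sd_low = 0.93,
                         erd2_mean_high = -0.06, erd2_sd_high = 0.70,
                         erd2_mean_low = 1.12, erd2_sd_low = 0.72,
                         trial_count = 10, movement_s = 3, rest_s = 7,
                         fs_eeg_emg = 1000, fs_angle = 50,
                         beta_band = c(14, 20),
                         baseline_power = 2.0, bg_sd = 2.0,
                         blink_gain = 0.05, emg_mod_depth = 0.3,
                         angle_noise_sd = 0.05,
                         biomech_params = list(
                           angle_change  = c(34.26, 9.25, 25.36, 9.43),
                           peak_dorsi_vel = c(83.5280, 30.7186, 50.5730, 13.4579),
                           peak_inv_vel  = c(55.9404, 20.1703, 35.4288, 11.5939),
                           post_to_change = c(2.23, 0.88, 3.51, 1.75),
                           ic_inversion  = c(2.51, 1.45, 4.72, 2.56),
                           gait_speed    = c(1.20, 0.17, 1.08, 0.16)),
                         empirical = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  if (target_cmc_high < 0 || target_cmc_high > 1 ||
      target_cmc_low < 0 || target_cmc_low > 1)
    stop_cmc("target coherences must lie in [0, 1]", class = "cmcgait_config_error")
  sds <- c(cmc_sd, erd_sd_high, erd_sd_low, erd2_sd_high, erd2_sd_low,
           vapply(biomech_params, function(p) p[c(2, 4)], numeric(2)))
  if (any(sds < 0))
    stop_cmc("all SDs must be >= 0", class = "cmcgait_config_error")
  if (movement_s <= 0 || rest_s < 0 || trial_count < 1)
    stop_cmc("inconsistent trial timing", class = "cmcgait_config_error")
  if (fs_angle <= 0 || fs_eeg_emg <= 0 ||
      abs(fs_angle * 0.5 - round(fs_angle * 0.5)) > 1e-9)
    stop_cmc("fs_angle must divide the 500 ms epoch-window boundaries",
             class = "cmcgait_config_error")
  class(cfg) <- "synth_config"
  cfg
}

#' Population coherence of a shared-drive pair
#'
#' For the generative model `x = gain_x * s + n_x`, `y = gain_y * s + n_y`
#' with a shared zero-mean drive `s` and independent noises, the
#' magnitude-squared coherence at a frequency where the spectral densities
#' are `shared_power`, `noise_power_x`, `noise_power_y` is
#' \deqn{C = g_x^2 g_y^2 P_{ss}^2 / ((g_x^2 P_{ss} + P_{n_x})(g_y^2 P_{ss} + P_{n_y}))}
#' This closed form is what the generator inverts to turn a target coherence
#' into noise variances.
#'
#' @param shared_power spectral density of the shared drive (>= 0).
#' @param noise_power_x,noise_power_y independent noise spectral densities
#'   (>= 0).
#' @param gain_x,gain_y channel gains.
#' @return Coherence value in [0, 1].
#' @examples
#' expected_coherence(1, 0, 0)    # 1: noise-free shared drive
#' expected_coherence(1, 1, 1)    # 0.25
#' @export
expected_coherence <- function(shared_power, noise_power_x, noise_power_y,
                               gain_x = 1, gain_y = 1) {
  if (shared_power < 0 || noise_power_x < 0 || noise_power_y < 0)
    stop_cmc("powers must be >= 0", class = "cmcgait_parameter_error")
  px <- gain_x^2 * shared_power + noise_power_x
  py <- gain_y^2 * shared_power + noise_power_y
  if (px == 0 || py == 0)
    stop_cmc("all-zero channel power; coherence undefined",
             class = "cmcgait_undefined_coherence_error")
  (gain_x^2 * gain_y^2 * shared_power^2) / (px * py)
}

# Symmetric-noise inversion: noise variance per channel such that
# expected_coherence(1, s2, s2) == target.
solve_symmetric_noise <- function(target) {
  stopifnot(target > 0, target <= 1)
  1 / sqrt(target) - 1
}

# Invert the first-order bias of the N-segment MSC estimator:
# E[estimate] ~ C + (1 - C)^2 / N * (1 + 2 C / N). Given a target on the
# estimated scale, return the population coherence to plant.
msc_population_for_estimate <- function(c_est, n_segments) {
  f <- function(C) C + (1 - C)^2 / n_segments * (1 + 2 * C / n_segments) - c_est
  if (f(0) >= 0) return(0)
  stats::uniroot(f, c(0, c_est), tol = 1e-10)$root
}

# --- calibration of the generator against the package's own estimators ----

calib_env <- new.env(parent = emptyenv())

# Long stationary surrogates, fixed internal seed. Returns the constants
# that map planted variances to measured wavelet band power and to in-band
# variance fractions, plus the rectified-EMG carrier statistics.
synth_calibration <- function(fs = 1000, beta_band = c(14, 20),
                              freqs = 14:20, cycles = 7,
                              emg_band = c(5, 300)) {
  key <- paste(fs, paste(beta_band, collapse = "-"),
               paste(range(freqs), collapse = "-"), cycles,
               paste(emg_band, collapse = "-"), sep = "|")
  if (!is.null(calib_env[[key]])) return(calib_env[[key]])
  cal <- with_seed(987654321, {
    n <- 2^17
    nyq <- fs / 2
    bf <- signal::butter(4, beta_band / nyq, type = "pass")
    unitize <- function(x) x / stats::sd(x)
    bandproc <- unitize(as.numeric(signal::filtfilt(bf, stats::rnorm(n))))
    white <- unitize(stats::rnorm(n))
    wav_gain <- function(x) {
      mean(vapply(freqs, function(f) {
        k <- morlet_kernel(f, fs, cycles)
        resp <- conv_same(x, k)
        core <- length(k):(length(x) - length(k))
        mean(Mod(resp[core])^2)
      }, numeric(1)))
    }
    hp <- signal::butter(4, emg_band[1] / nyq, type = "high")
    lp <- signal::butter(4, emg_band[2] / nyq, type = "low")
    carrier <- unitize(as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, stats::rnorm(n)))))
    r <- abs(carrier)
    fm <- fm_process(n, fs, beta_band, phi0 = 0.7)
    # band-bin spectral shapes of the FM rhythm and the Gaussian band noise
    # on the analysis grid (3 s Hann segments), for bin-wise coherence
    # inversion
    psd_bins <- function(x, L = 3 * fs) {
      w <- hann_window(L)
      nseg <- floor(length(x) / L)
      acc <- 0
      for (k in seq_len(nseg)) {
        seg <- x[((k - 1) * L + 1):(k * L)]
        acc <- acc + Mod(stats::fft((seg - mean(seg)) * w))^2
      }
      f <- (0:(L - 1)) * fs / L
      sel <- f >= beta_band[1] & f <= beta_band[2]
      (acc / nseg)[sel]
    }
    list(k_beta = wav_gain(bandproc),            # wavelet band power per unit band variance
         g_bg = wav_gain(white),                 # same, per unit white variance
         k_det = wav_gain(fm),                   # same, per unit FM-rhythm variance
         v_u = stats::var(as.numeric(signal::filtfilt(bf, bandproc))),
         v_white_band = stats::var(as.numeric(signal::filtfilt(bf, white))),
         v_det_band = stats::var(as.numeric(signal::filtfilt(bf, fm))),
         rho_bins = psd_bins(bandproc) / psd_bins(fm),
         mu_rect = mean(r),                      # E|carrier|
         w_band = stats::var(as.numeric(signal::filtfilt(bf, r - mean(r)))))
  })
  calib_env[[key]] <- cal
  cal
}

# Group draws. empirical = TRUE realizes the group as randomly permuted
# normal scores standardized to the exact configured moments: the sample
# then has precisely the summary statistics (and the normal shape) that a
# study reporting them as mean +/- SD would have had. empirical = FALSE
# draws i.i.d. from the group Gaussian.
draw_group <- function(n, mean, sd, empirical, seed) {
  with_seed(seed, {
    if (empirical && n >= 2) {
      q <- stats::qnorm(stats::ppoints(n))
      x <- ((q - mean(q)) / stats::sd(q))[sample.int(n)]
    } else {
      x <- stats::rnorm(n)
    }
    mean + sd * x
  })
}

draw_two_groups <- function(cfg, mean_high, sd_high, mean_low, sd_low, stream) {
  c(draw_group(cfg$n_high, mean_high, sd_high, cfg$empirical,
               substream_seed(cfg$seed, 1L, stream)),
    draw_group(cfg$n_low, mean_low, sd_low, cfg$empirical,
               substream_seed(cfg$seed, 2L, stream)))
}

# Planted per-subject parameters for the whole cohort (ground truth).
synth_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_high + cfg$n_low
  bp <- cfg$biomech_params
  truth <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = factor(rep(c("high", "low"), c(cfg$n_high, cfg$n_low)),
                   levels = c("high", "low")),
    cmc = draw_two_groups(cfg, cfg$target_cmc_high, cfg$cmc_sd,
                          cfg$target_cmc_low, cfg$cmc_sd, 1L),
    erd_d1 = draw_two_groups(cfg, cfg$erd_mean_high, cfg$erd_sd_high,
                             cfg$erd_mean_low, cfg$erd_sd_low, 2L),
    erd_d2 = draw_two_groups(cfg, cfg$erd2_mean_high, cfg$erd2_sd_high,
                             cfg$erd2_mean_low, cfg$erd2_sd_low, 3L),
    angle_change = draw_two_groups(cfg, bp$angle_change[1], bp$angle_change[2],
                                   bp$angle_change[3], bp$angle_change[4], 4L),
    peak_dorsi_vel = draw_two_groups(cfg, bp$peak_dorsi_vel[1], bp$peak_dorsi_vel[2],
                                     bp$peak_dorsi_vel[3], bp$peak_dorsi_vel[4], 5L),
    peak_inv_vel = draw_two_groups(cfg, bp$peak_inv_vel[1], bp$peak_inv_vel[2],
                                   bp$peak_inv_vel[3], bp$peak_inv_vel[4], 6L),
    post_to_change = draw_two_groups(cfg, bp$post_to_change[1], bp$post_to_change[2],
                                     bp$post_to_change[3], bp$post_to_change[4], 7L),
    ic_inversion = draw_two_groups(cfg, bp$ic_inversion[1], bp$ic_inversion[2],
                                   bp$ic_inversion[3], bp$ic_inversion[4], 8L),
    gait_speed = draw_two_groups(cfg, bp$gait_speed[1], bp$gait_speed[2],
                                 bp$gait_speed[3], bp$gait_speed[4], 9L))
  truth$cmc <- pmin(pmax(truth$cmc, 0.02), 0.98)
  # planted kinematics must stay physical
  truth$angle_change <- pmax(truth$angle_change, 2)
  truth$peak_dorsi_vel <- pmax(pmin(truth$peak_dorsi_vel, 10 * truth$angle_change),
                               truth$angle_change / 2)
  truth$peak_inv_vel <- pmax(truth$peak_inv_vel, 2)
  truth$post_to_change <- pmax(truth$post_to_change, 0.2)
  truth$gait_speed <- pmax(truth$gait_speed, 0.3)
  truth
}

# beta-power deviation from baseline (microvolt^2) at time tau (s) relative
# to movement onset: 0 before -0.5 s, d1 over the late preparation window,
# linear to d2 through early execution, then decay back to baseline.
erd_delta <- function(tau, d1, d2) {
  out <- numeric(length(tau))
  i <- tau >= -0.5 & tau < 0;  out[i] <- d1
  i <- tau >= 0 & tau < 0.5;   out[i] <- d1 + (d2 - d1) * tau[i] / 0.5
  i <- tau >= 0.5 & tau < 1;   out[i] <- d2
  i <- tau >= 1 & tau < 3;     out[i] <- d2 * (1 - (tau[i] - 1) / 2)
  out
}

# Trapezoidal-velocity ramp: angle at time tau of a movement that
# accelerates linearly to V over t_a, holds V for t_p, decelerates over
# t_a. Total excursion V * (t_a + t_p). Exactly linear around peak
# velocity, so discrete centered differences recover V exactly.
trap_ramp <- function(tau, V, t_a, t_p) {
  A <- V * (t_a + t_p)
  t_tot <- 2 * t_a + t_p
  out <- numeric(length(tau))
  i <- tau > 0 & tau < t_a
  out[i] <- 0.5 * V * tau[i]^2 / t_a
  i <- tau >= t_a & tau < t_a + t_p
  out[i] <- 0.5 * V * t_a + V * (tau[i] - t_a)
  i <- tau >= t_a + t_p & tau < t_tot
  out[i] <- A - 0.5 * V * (t_tot - tau[i])^2 / t_a
  out[tau >= t_tot] <- A
  out
}

grid_floor <- function(x, step) floor(x / step + 1e-9) * step

# Dorsiflexion-task angle trace for one subject (noise added by caller).
synth_task_angles <- function(cfg, onsets, duration, A, V, Vi) {
  fs <- cfg$fs_angle
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  dorsi <- numeric(length(t))
  inv <- numeric(length(t))
  ratio <- A / V
  t_a <- max(0.04, min(0.2, grid_floor(ratio - 0.06, 1 / fs)))
  t_p <- ratio - t_a
  amp_i <- Vi * 0.14
  for (t0 in onsets) {
    tau <- t - t0
    up <- trap_ramp(tau, V, t_a, t_p)
    # hold at A until movement end, then release back over 1 s
    rel <- tau > cfg$movement_s
    hold <- pmin(up, A)
    hold[rel] <- A * pmax(0, 1 - (tau[rel] - cfg$movement_s))
    dorsi <- dorsi + hold
    # frontal-plane bump: up and straight back down, both at peak rate Vi
    tau_i <- tau - 0.1
    bump <- trap_ramp(tau_i, Vi, 0.08, 0.06) -
      trap_ramp(tau_i - 0.32, Vi, 0.08, 0.06)
    inv <- inv + pmax(bump, 0)
  }
  list(time = t, dorsi = dorsi, inv = inv)
}

band_process <- function(n, filt) {
  x <- as.numeric(signal::filtfilt(filt, stats::rnorm(n)))
  x / stats::sd(x)
}

# Constant-amplitude band rhythm: a unit-variance sinusoid whose
# instantaneous frequency sweeps the band triangularly (uniform occupancy).
# Its sample power is deterministic, so a power template it carries is
# planted with essentially no estimator variance; the sweep period is
# incommensurate with the 10 s trial spacing so segments see independent
# phases.
fm_process <- function(n, fs, band = c(14, 20), period = 1.37, phi0 = 0) {
  t <- (0:(n - 1L)) / fs
  u <- (t / period + phi0) %% 1
  tri <- ifelse(u < 0.5, 2 * u, 2 - 2 * u)           # 0..1..0
  f_inst <- band[1] + (band[2] - band[1]) * tri
  phase <- 2 * pi * cumsum(f_inst) / fs
  sqrt(2) * cos(phase)
}

#' Generate raw recordings for a synthetic cohort
#'
#' For each subject: a 1000 Hz `signal_record` with channels Cz, TA, MG,
#' EOG_up, EOG_down and a 50 Hz ankle `angle_trace`, over a session of
#' `trial_count` dorsiflexion trials (3 s movement, 7 s rest, 5 s lead-in).
#' The Cz beta rhythm is a band-limited constant-amplitude oscillation
#' whose envelope carries the subject's planted event-related power change
#' exactly; the TA amplitude modulation shares this rhythm as a common
#' drive, mixed with independent band-limited Gaussian noise whose level is
#' calibrated (bin-wise, against the package's own spectral estimators) so
#' that the 10-segment Cz-TA coherence estimate targets the subject's
#' planted value. EMG is amplitude-modulated broadband noise, so full-wave
#' rectification recovers the coupled envelope; EOG blinks leak into Cz
#' with a fixed gain.
#'
#' @param cfg a [synth_config()].
#' @return list with `subjects` (per subject: `record`, `angle`, `onsets`)
#'   and `truth` (the planted ground-truth data.frame).
#' @export
synth_cohort_signals <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- synth_ground_truth(cfg)
  cal <- synth_calibration(cfg$fs_eeg_emg, cfg$beta_band,
                           freqs = seq(cfg$beta_band[1], cfg$beta_band[2]),
                           cycles = 7, emg_band = c(5, 300))
  fs <- cfg$fs_eeg_emg
  nyq <- fs / 2
  bf <- signal::butter(4, cfg$beta_band / nyq, type = "pass")
  period <- cfg$movement_s + cfg$rest_s
  lead_in <- 5
  duration <- lead_in + cfg$trial_count * period
  onsets <- lead_in + (seq_len(cfg$trial_count) - 1L) * period
  n <- round(duration * fs)
  t <- (0:(n - 1L)) / fs
  # time relative to the enclosing trial's onset (NA outside +/- epoch span)
  tau <- rep(Inf, n)
  for (t0 in onsets) {
    sel <- t >= t0 - 3 & t < t0 + period - 3
    tau[sel] <- t[sel] - t0
  }
  subjects <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    s_seed <- substream_seed(cfg$seed, i, stream = 100L)
    subjects[[i]] <- with_seed(s_seed, {
      # --- planted beta power time course (measured scale, microvolt^2)
      bg_pow <- cal$g_bg * cfg$bg_sd^2
      p_net <- pmax(cfg$baseline_power +
                      erd_delta(tau, tr$erd_d1, tr$erd_d2) - bg_pow, 0.05)
      move_sel <- tau >= 0 & tau < cfg$movement_s
      # The Cz beta rhythm is a constant-amplitude band-swept sinusoid whose
      # envelope carries the planted power template exactly; all coherence
      # noise is placed on the EMG side, so the Cz beta power estimate is
      # essentially deterministic while the Cz-TA coherence is still set by
      # the mixing below.
      v_det <- p_net / cal$k_det
      s_fm <- fm_process(n, fs, cfg$beta_band, phi0 = stats::runif(1))
      # --- coherence calibration on the movement window
      c_pop <- msc_population_for_estimate(tr$cmc, cfg$trial_count)
      # EEG-side dilution: broadband background power inside the beta band
      p_beta_inband <- mean(v_det[move_sel]) * cal$v_det_band
      d_x <- p_beta_inband / (p_beta_inband + cfg$bg_sd^2 * cal$v_white_band)
      # EMG-side dilution: rectified-carrier noise inside the beta band
      g <- cfg$emg_mod_depth
      num_y <- (g * cal$mu_rect)^2 * cal$v_u
      d_y <- num_y / (num_y + cal$w_band * (1 + g^2))
      c_drive <- min(max(c_pop / (d_x * d_y), 1e-4), 0.995)
      # bin-wise inversion for the EMG-side mixing noise: solve s2 so that
      # the band-mean of 1 / (1 + s2 * rho(f)) equals the drive coherence
      s2 <- stats::uniroot(function(s) mean(1 / (1 + s * cal$rho_bins)) - c_drive,
                           c(1e-8, 1e8), tol = 1e-10)$root
      u_y <- (s_fm + sqrt(s2) * band_process(n, bf)) / sqrt(1 + s2)
      det_part <- sqrt(v_det) * s_fm
      # --- EOG blinks
      blink <- numeric(n)
      tb <- lead_in / 2
      while (tb < duration - 1) {
        ib <- round(tb * fs)
        w <- round(0.4 * fs)
        idx <- max(1, ib - w):min(n, ib + w)
        blink[idx] <- blink[idx] +
          stats::runif(1, 80, 160) * exp(-((idx - ib) / (0.08 * fs))^2 / 2)
        tb <- tb + stats::runif(1, 2.5, 6)
      }
      # --- channels
      cz <- det_part + cfg$bg_sd * stats::rnorm(n) + cfg$blink_gain * blink
      act <- as.numeric(move_sel)
      m_env <- 8 * (1 - act) + 50 * act * pmax(1 + g * u_y, 0.05)
      ta <- m_env * stats::rnorm(n)
      mg_env <- 6 + 10 * act
      mg <- mg_env * stats::rnorm(n)
      eog_up <- blink + 5 * stats::rnorm(n)
      eog_down <- -0.6 * blink + 5 * stats::rnorm(n)
      rec <- signal_record(rbind(Cz = cz, TA = ta, MG = mg,
                                 EOG_up = eog_up, EOG_down = eog_down),
                           c("Cz", "TA", "MG", "EOG_up", "EOG_down"),
                           rate = fs)
      # --- ankle angles (50 Hz)
      ang <- synth_task_angles(cfg, onsets, duration, tr$angle_change,
                               tr$peak_dorsi_vel, tr$peak_inv_vel)
      na <- length(ang$time)
      trace <- angle_trace(ang$time,
                           ang$dorsi + cfg$angle_noise_sd * stats::rnorm(na),
                           ang$inv + cfg$angle_noise_sd * stats::rnorm(na),
                           rate = cfg$fs_angle)
      list(subject = tr$subject, record = rec, angle = trace, onsets = onsets)
    })
  }
  names(subjects) <- truth$subject
  list(subjects = subjects, truth = truth)
}

#' Sample a subject-by-window feature table directly
#'
#' Bypasses signal synthesis: features for each of the 11 epoch windows are
#' drawn from per-group Gaussians. By default the -500--0 ms and
#' 500--1000 ms windows use the configured group distributions and the
#' remaining windows share a common non-discriminative distribution, so
#' group separation exists only where it is planted.
#'
#' @param cfg a [synth_config()].
#' @param windows window labels (default [feature_windows()]`$window`).
#' @param null_mean,null_sd distribution of the non-discriminative windows
#'   (default 0.3 / 0.8 for both groups).
#' @return data.frame with columns `subject`, `window`, `value`, `group`.
#' @export
synth_feature_table <- function(cfg = synth_config(), windows = feature_windows()$window,
                                null_mean = 0.3, null_sd = 0.8) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_high + cfg$n_low
  if (n < 4)
    stop_cmc("need at least 4 subjects", class = "cmcgait_too_few_subjects_error")
  subject <- sprintf("S%02d", seq_len(n))
  group <- rep(c("high", "low"), c(cfg$n_high, cfg$n_low))
  out <- list()
  for (k in seq_along(windows)) {
    w <- windows[k]
    vals <- if (w == "-500~0 ms") {
      draw_two_groups(cfg, cfg$erd_mean_high, cfg$erd_sd_high,
                      cfg$erd_mean_low, cfg$erd_sd_low, 200L + k)
    } else if (w == "500~1000 ms") {
      draw_two_groups(cfg, cfg$erd2_mean_high, cfg$erd2_sd_high,
                      cfg$erd2_mean_low, cfg$erd2_sd_low, 200L + k)
    } else {
      draw_two_groups(cfg, null_mean, null_sd, null_mean, null_sd, 200L + k)
    }
    out[[k]] <- data.frame(subject = subject, window = w, value = vals,
                           group = group)
  }
  do.call(rbind, out)
}

#' Generate gait trials for a synthetic cohort
#'
#' Ten gait cycles per subject (11 initial contacts) of a 50 Hz two-plane
#' ankle trace, with the planted post-toe-off dorsiflexion change and
#' initial-contact inversion angle embedded exactly (plateaued segments on
#' the sample grid), plus IC/TO event times and per-pass traversal times for
#' the 8 m walking path.
#'
#' @param cfg a [synth_config()].
#' @param n_cycles gait cycles per subject (default 10).
#' @param stride_s stride (cycle) duration in seconds (default 1.12).
#' @param pass_length_m walking-path length (default 8).
#' @return list with `subjects` (per subject: `angle`, `ic_times`,
#'   `to_times`, `pass_length_m`, `pass_times_s`) and `truth`.
#' @export
synth_gait_trials <- function(cfg = synth_config(), n_cycles = 10,
                              stride_s = 1.12, pass_length_m = 8) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs_angle
  stride_s <- grid_floor(stride_s, 1 / fs)
  to_frac_s <- grid_floor(0.62 * stride_s, 1 / fs)
  post_win <- 0.2 * stride_s
  if (post_win < 4 / fs)
    stop_cmc("cycle too short for the post-TO metric window",
             class = "cmcgait_config_error")
  truth <- synth_ground_truth(cfg)
  lead <- 1
  duration <- 2 * lead + n_cycles * stride_s
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  ic_times <- lead + (0:n_cycles) * stride_s
  to_times <- ic_times[seq_len(n_cycles)] + to_frac_s
  plateau_end <- grid_floor(post_win, 1 / fs) + 0.04  # hold past the window end
  subjects <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    s_seed <- substream_seed(cfg$seed, i, stream = 300L)
    subjects[[i]] <- with_seed(s_seed, {
      dorsi <- numeric(length(t))
      inv <- numeric(length(t))
      to_angle <- -10
      for (k in seq_len(n_cycles)) {
        t0 <- ic_times[k]; t1 <- ic_times[k + 1L]; tto <- to_times[k]
        seg <- t >= t0 & t < t1
        tt <- t[seg]
        y <- numeric(length(tt))
        # stance: drop from 0 at IC to the toe-off angle
        stance <- tt < tto
        y[stance] <- to_angle * (tt[stance] - t0) / (tto - t0)
        # swing initiation: rise by the planted change, plateau past the
        # metric window, then return towards neutral for the next IC
        rise_end <- tto + 0.12
        hold_end <- tto + plateau_end
        sw <- tt >= tto
        ts <- tt[sw]
        peak <- to_angle + tr$post_to_change
        yswing <- ifelse(ts < rise_end,
                         to_angle + (peak - to_angle) * (ts - tto) / (rise_end - tto),
                  ifelse(ts < hold_end, peak,
                         peak - peak * (ts - hold_end) / (t1 - hold_end)))
        y[sw] <- yswing
        dorsi[seg] <- y
        # inversion: plateau of the planted angle around each IC
        iv <- pmax(0, 1 - abs(tt - t0) / 0.2) # triangular rise
        iv[abs(tt - t0) <= 0.02 + 1e-9] <- 1
        inv[seg] <- pmax(inv[seg], tr$ic_inversion * iv)
      }
      na <- length(t)
      trace <- angle_trace(t,
                           dorsi + cfg$angle_noise_sd * stats::rnorm(na),
                           inv + cfg$angle_noise_sd * stats::rnorm(na),
                           rate = fs)
      list(subject = tr$subject, angle = trace, ic_times = ic_times,
           to_times = to_times, pass_length_m = pass_length_m,
           pass_times_s = rep(pass_length_m / tr$gait_speed, 10))
    })
  }
  names(subjects) <- truth$subject
  list(subjects = subjects, truth = truth)
}
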