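# Filtering, rectification, EOG regression, onset detection, epoching.

rms <- function(x) sqrt(mean(x^2))

test_that("canned filters attenuate and pass the right bands", {
  rate <- 1000
  t <- (0:9999) / rate
  mid <- 2000:8000
  rec60 <- signal_record(rbind(Cz = sin(2 * pi * 60 * t)), "Cz", rate)
  out60 <- filter_signal(rec60, "notch60")
  expect_lt(rms(out60$samples[1, mid]) / rms(rec60$samples[1, mid]), 0.05)

  rec17 <- signal_record(rbind(Cz = sin(2 * pi * 17 * t)), "Cz", rate)
  out17 <- filter_signal(rec17, "eeg_band")
  expect_equal(rms(out17$samples[1, mid]) / rms(rec17$samples[1, mid]), 1,
               tolerance = 0.05)
  # the notch leaves 17 Hz untouched
  out17n <- filter_signal(rec17, "notch60")
  expect_equal(rms(out17n$samples[1, mid]) / rms(rec17$samples[1, mid]), 1,
               tolerance = 0.01)

  recdc <- signal_record(rbind(TA = rep(1, 10000)), "TA", rate)
  outdc <- filter_signal(recdc, "emg_band")
  expect_lt(max(abs(outdc$samples[1, mid])), 1e-6)

  # cutoff above Nyquist refused
  rec_slow <- signal_record(rbind(TA = rnorm(1000)), "TA", rate = 400)
  expect_error(filter_signal(rec_slow, "emg_band"),
               class = "cmcgait_parameter_error")
})

test_that("zero-phase property: time reversal commutes with filtering", {
  # compared away from the record edges, where finite-length start-up
  # transients differ between the two directions
  set.seed(1)
  x <- rnorm(5000)
  rec <- signal_record(rbind(TA = x), "TA", 1000)
  rev_rec <- signal_record(rbind(TA = rev(x)), "TA", 1000)
  a <- filter_signal(rec, "emg_band")$samples[1, ]
  b <- rev(filter_signal(rev_rec, "emg_band")$samples[1, ])
  mid <- 1000:4000
  expect_lt(rms(a[mid] - b[mid]), 1e-6)
})

test_that("rectify takes absolute values on selected channels only", {
  rec <- signal_record(rbind(Cz = c(-1, 2, -3), TA = c(-1, 2, -3)),
                       c("Cz", "TA"), 1000)
  out <- rectify(rec, "TA")
  expect_equal(unname(out$samples["TA", ]), c(1, 2, 3))
  expect_equal(unname(out$samples["Cz", ]), c(-1, 2, -3))
  expect_equal(rectify(out, "TA")$samples["TA", ], out$samples["TA", ])
  expect_error(rectify(rec, "MG"), class = "cmcgait_channel_error")
})

test_that("full-wave rectified sine has mean 2A/pi", {
  t <- (0:99999) / 1000
  A <- 3
  rec <- signal_record(rbind(TA = A * sin(2 * pi * 10 * t)), "TA", 1000)
  expect_equal(mean(rectify(rec, "TA")$samples[1, ]), 2 * A / pi,
               tolerance = 1e-3)
})

test_that("EOG regression removes mixed ocular artifact from EEG", {
  set.seed(2)
  n <- 20000
  clean <- as.numeric(signal::filtfilt(signal::butter(4, c(14, 20) / 500, "pass"),
                                       rnorm(n)))
  eog <- as.numeric(stats::filter(rnorm(n), rep(1 / 50, 50), sides = 2))
  eog[is.na(eog)] <- 0
  rec <- signal_record(rbind(Cz = clean + 0.5 * eog, TA = rnorm(n),
                             EOG_up = eog, EOG_down = -0.6 * eog),
                       c("Cz", "TA", "EOG_up", "EOG_down"), 1000)
  out <- regress_eog(rec)
  expect_lt(abs(cor(out$samples["Cz", ], eog)), 0.05)
  expect_equal(out$samples["TA", ], rec$samples["TA", ])

  # all-zero EOG leaves EEG unchanged
  rec0 <- rec
  rec0$samples["EOG_up", ] <- 0
  rec0$samples["EOG_down", ] <- 0
  out0 <- regress_eog(rec0)
  expect_equal(out0$samples["Cz", ], rec0$samples["Cz", ], tolerance = 1e-9)

  # EEG that is a pure EOG copy regresses to (near) zero fluctuation
  recp <- rec
  recp$samples["Cz", ] <- 2 * eog
  outp <- regress_eog(recp)
  expect_lt(sd(outp$samples["Cz", ]), 1e-8)

  expect_error(regress_eog(rec["Cz"]), class = "cmcgait_channel_error")
  expect_identical(regress_eog(rec, enabled = FALSE), rec)
})

test_that("onset detector finds ramp crossings at the analytic time", {
  rate <- 50
  t <- seq(0, 20, by = 1 / rate)
  slope <- 100                       # deg/s
  d <- pmax(0, pmin(t - 2, 0.4)) * slope
  tr <- angle_trace(t, d, 0 * t, rate)
  onsets <- detect_onset(tr, threshold_deg = 2, min_hold_s = 0.1)
  expect_length(onsets, 1)
  expect_equal(onsets, 2 + 2 / slope, tolerance = 0.05)

  flat <- angle_trace(t, 0 * t, 0 * t, rate)
  expect_length(detect_onset(flat), 0)
})

test_that("onset detector recovers the ten trials of a synthetic session", {
  cfg <- synth_config(n_high = 1, n_low = 1, seed = 8)
  coh <- synth_cohort_signals(cfg)
  s <- coh$subjects[[1]]
  det <- detect_onset(s$angle)
  expect_length(det, 10)
  expect_equal(diff(det), rep(10, 9), tolerance = 0.1)
  expect_true(all(abs(det - s$onsets) < 0.15))
})

test_that("epoching cuts bit-identical windows and drops short margins", {
  rec <- test_record(12000)
  expect_warning(ep <- epoch_trials(rec, c(1, 5, 8), window = c(-3, 3)),
                 "dropped 1")
  expect_equal(dim(ep$data), c(2, 2, 6000))
  expect_equal(ep$time[1], -3)
  expect_equal(ep$time[2] - ep$time[1], 1e-3)
  # sample values identical to the source (no resampling)
  src <- rec$samples["Cz", 2001:8000]
  expect_identical(as.numeric(ep$data[1, "Cz", ]), as.numeric(src))
  expect_error(suppressWarnings(epoch_trials(rec, c(0.5), window = c(-3, 3))),
               class = "cmcgait_epoching_error")
})

test_that("gait epoching pairs consecutive ICs and requires a contained TO", {
  t <- seq(0, 14, by = 0.02)
  tr <- angle_trace(t, sin(t), cos(t), 50)
  ic <- 1 + 0:10 * 1.2
  to <- ic[1:10] + 0.7
  cycles <- epoch_gait(tr, ic, to)
  expect_length(cycles, 10)
  expect_equal(cycles[[1]]$to, to[1])
  expect_equal(cycles[[3]]$end - cycles[[3]]$start, 1.2)

  expect_error(epoch_gait(tr, ic[1], to), class = "cmcgait_epoching_error")
  expect_warning(c9 <- epoch_gait(tr, ic, to[-1]), "dropped 1")
  expect_length(c9, 9)
})
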