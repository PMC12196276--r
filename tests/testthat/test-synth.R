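# Synthetic-cohort generator: closed-form coherence, determinism,
# distribution planting, ground-truth bookkeeping.

test_that("expected_coherence matches the closed form of the shared-drive model", {
  expect_equal(expected_coherence(1, 0, 0), 1.0)
  expect_equal(expected_coherence(1, 1, 1), 0.25)
  expect_equal(expected_coherence(2, 1, 3, gain_x = 0.5, gain_y = 2),
               (0.25 * 4 * 4) / ((0.5 + 1) * (8 + 3)))
  expect_error(expected_coherence(0, 0, 0),
               class = "cmcgait_undefined_coherence_error")
  expect_error(expected_coherence(-1, 0, 0), class = "cmcgait_parameter_error")
})

test_that("symmetric noise inversion hits a 0.26 target", {
  s2 <- cmcgait:::solve_symmetric_noise(0.26)
  expect_equal(s2, 0.9612, tolerance = 1e-3)
  expect_equal(expected_coherence(1, s2, s2), 0.26, tolerance = 1e-9)
})

test_that("generation is bit-identical for the same config and seed", {
  cfg <- tiny_config()
  a <- synth_cohort_signals(cfg)
  b <- synth_cohort_signals(cfg)
  expect_identical(a, b)
  ga <- synth_gait_trials(cfg)
  gb <- synth_gait_trials(cfg)
  expect_identical(ga, gb)
  fa <- synth_feature_table(cfg)
  expect_identical(fa, synth_feature_table(cfg))
  # a different seed changes the draws
  cfg2 <- tiny_config(); cfg2$seed <- 43
  expect_false(identical(synth_feature_table(cfg2), fa))
})

test_that("generated records expose the expected channels and rates", {
  coh <- synth_cohort_signals(tiny_config())
  expect_length(coh$subjects, 6)
  s <- coh$subjects[[1]]
  expect_setequal(s$record$channels, c("Cz", "TA", "MG", "EOG_up", "EOG_down"))
  expect_equal(s$record$rate, 1000)
  expect_equal(s$angle$rate, 50)
  expect_length(s$onsets, 3)
  # angle and signal clocks cover the same session
  expect_equal(ncol(s$record$samples) / 1000,
               length(s$angle$time) / 50, tolerance = 0.01)
})

test_that("ground truth has one row per subject with matching labels", {
  cfg <- tiny_config()
  coh <- synth_cohort_signals(cfg)
  expect_equal(nrow(coh$truth), 6)
  expect_equal(names(coh$subjects), coh$truth$subject)
  expect_equal(as.vector(table(coh$truth$group)), c(3, 3))
  expect_true(all(coh$truth$cmc >= 0 & coh$truth$cmc <= 1))
  gait <- synth_gait_trials(cfg)
  expect_equal(gait$truth$subject, coh$truth$subject)
  expect_equal(gait$truth$group, coh$truth$group)
})

test_that("feature table defaults give 23 rows per window, 12 high / 11 low", {
  tab <- synth_feature_table(synth_config(seed = 2))
  expect_equal(nrow(tab), 23 * 11)
  one <- tab[tab$window == "-500~0 ms", ]
  expect_equal(as.vector(table(one$group)), c(12, 11))
  expect_error(synth_feature_table(synth_config(n_high = 2, n_low = 1)),
               class = "cmcgait_too_few_subjects_error")
})

test_that("zero-SD features collapse onto the group means", {
  cfg <- synth_config(erd_sd_high = 1e-12, erd_sd_low = 1e-12, seed = 2)
  tab <- synth_feature_table(cfg)
  one <- tab[tab$window == "-500~0 ms", ]
  expect_equal(one$value[one$group == "high"], rep(-0.40, 12), tolerance = 1e-6)
  expect_equal(one$value[one$group == "low"], rep(1.03, 11), tolerance = 1e-6)
})

test_that("sampled feature moments converge to the configured moments", {
  cfg <- synth_config(n_high = 5000, n_low = 5000, seed = 3, empirical = FALSE)
  tab <- synth_feature_table(cfg, windows = "-500~0 ms")
  h <- tab$value[tab$group == "high"]
  l <- tab$value[tab$group == "low"]
  expect_equal(mean(h), -0.40, tolerance = 0.02)
  expect_equal(sd(h), 0.24, tolerance = 0.02)
  expect_equal(mean(l), 1.03, tolerance = 0.03)
  expect_equal(sd(l), 0.93, tolerance = 0.03)
  # empirical mode pins the moments exactly
  cfg2 <- synth_config(seed = 3)
  tab2 <- synth_feature_table(cfg2, windows = "-500~0 ms")
  expect_equal(mean(tab2$value[tab2$group == "high"]), -0.40, tolerance = 1e-9)
  expect_equal(sd(tab2$value[tab2$group == "high"]), 0.24, tolerance = 1e-9)
})

test_that("gait generator plants group ordering and zero-variance cohorts", {
  bp <- list(angle_change = c(34.26, 9.25, 25.36, 9.43),
             peak_dorsi_vel = c(83.5, 30.7, 50.6, 13.5),
             peak_inv_vel = c(55.9, 20.2, 35.4, 11.6),
             post_to_change = c(2.23, 1e-12, 3.51, 1e-12),
             ic_inversion = c(2.51, 1e-12, 4.72, 1e-12),
             gait_speed = c(1.20, 1e-12, 1.08, 1e-12))
  cfg <- synth_config(n_high = 3, n_low = 3, biomech_params = bp,
                      angle_noise_sd = 0, seed = 17)
  gait <- synth_gait_trials(cfg)
  vals <- t(sapply(seq_along(gait$subjects), function(i) {
    g <- gait$subjects[[i]]
    cycles <- epoch_gait(g$angle, g$ic_times, g$to_times)
    gm <- gait_metrics(cycles, pass_length_m = g$pass_length_m,
                       pass_times_s = g$pass_times_s)
    gm$mean
  }))
  hi <- gait$truth$group == "high"
  # zero-variance config: all subjects within a group identical
  expect_lt(diff(range(vals[hi, "post_to_change"])), 1e-6)
  expect_lt(diff(range(vals[!hi, "ic_inversion"])), 1e-6)
  # printed direction: low > high for both gait metrics
  expect_lt(mean(vals[hi, "post_to_change"]), mean(vals[!hi, "post_to_change"]))
  expect_lt(mean(vals[hi, "ic_inversion"]), mean(vals[!hi, "ic_inversion"]))
})

test_that("invalid configurations are refused", {
  expect_error(synth_config(target_cmc_high = 1.2), class = "cmcgait_config_error")
  expect_error(synth_config(cmc_sd = -1), class = "cmcgait_config_error")
  expect_error(synth_config(movement_s = 0), class = "cmcgait_config_error")
  expect_error(synth_config(fs_angle = 3), class = "cmcgait_config_error")
})
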