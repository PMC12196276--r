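# Magnitude-squared coherence, confidence level, band summary, median split.

seg_matrix <- function(n, L, gen) t(vapply(seq_len(n), function(i) gen(L), numeric(L)))

test_that("self-coherence is 1 at every bin with power", {
  set.seed(1)
  x <- seg_matrix(10, 1000, function(L) rnorm(L))
  spec <- estimate_msc(x, x, rate = 1000)
  expect_true(all(spec$msc[spec$freq > 0 & spec$freq < 500] > 1 - 1e-9))
})

test_that("independent noise gives mean coherence near 1/N", {
  set.seed(2)
  N <- 10
  x <- seg_matrix(N, 3000, function(L) rnorm(L))
  y <- seg_matrix(N, 3000, function(L) rnorm(L))
  spec <- estimate_msc(x, y, rate = 1000)
  sel <- spec$freq > 1 & spec$freq < 499      # > 1000 interior bins
  expect_gt(sum(sel), 1000)
  expect_equal(mean(spec$msc[sel]), 1 / N, tolerance = 0.2)
})

test_that("null exceedance of the confidence level is about alpha", {
  set.seed(3)
  fracs <- replicate(2, {
    x <- seg_matrix(10, 3000, function(L) rnorm(L))
    y <- seg_matrix(10, 3000, function(L) rnorm(L))
    spec <- estimate_msc(x, y, rate = 1000)
    sel <- spec$freq > 1 & spec$freq < 499
    mean(spec$msc[sel] > spec$confidence_level)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)   # 5% +/- 2 points
})

test_that("msc is bounded and scale-invariant", {
  set.seed(4)
  for (i in 1:5) {
    x <- seg_matrix(4, 500, function(L) cumsum(rnorm(L)))
    y <- seg_matrix(4, 500, function(L) rnorm(L) + 0.3 * x[1, seq_len(L)])
    spec <- estimate_msc(x, y, rate = 1000)
    expect_true(all(spec$msc >= 0 & spec$msc <= 1, na.rm = TRUE))
    spec2 <- estimate_msc(37.5 * x, -0.004 * y, rate = 1000)
    expect_equal(spec$msc, spec2$msc, tolerance = 1e-9)
  }
})

test_that("degenerate segments are refused with the trial named", {
  x <- rbind(rnorm(100), rep(0, 100))
  y <- rbind(rnorm(100), rnorm(100))
  err <- expect_error(estimate_msc(x, y, rate = 1000),
                      class = "cmcgait_degenerate_segment_error")
  expect_match(conditionMessage(err), "trial 2")
  expect_error(estimate_msc(matrix(rnorm(100), 1), matrix(rnorm(100), 1), 1000),
               class = "cmcgait_parameter_error")
})

test_that("confidence level follows the closed form", {
  expect_equal(confidence_level(2, 0.95), 0.95)
  expect_equal(confidence_level(10, 0.95), 1 - 0.05^(1 / 9), tolerance = 1e-12)
  expect_equal(confidence_level(10, 0.95), 0.2831, tolerance = 1e-3)
  cl <- confidence_level(2:200, 0.95)
  expect_true(all(diff(cl) < 0))
  expect_lt(confidence_level(10000, 0.95), 1e-3)
  expect_error(confidence_level(1, 0.95), class = "cmcgait_parameter_error")
  expect_error(confidence_level(10, 1.2), class = "cmcgait_parameter_error")
})

test_that("band summary reduces the band as mean or peak", {
  spec <- structure(list(freq = seq(0, 50, by = 0.5),
                         msc = rep(0.5, 101), n_segments = 10, alpha = 0.95,
                         confidence_level = confidence_level(10, 0.95)),
                    class = "coherence_spectrum")
  expect_equal(band_summary(spec, c(14, 20), "mean")$value, 0.5)
  expect_equal(band_summary(spec, c(14, 20), "peak")$value, 0.5)
  spec$msc[spec$freq == 17] <- 0.9
  expect_equal(band_summary(spec, c(17, 17), "mean")$value, 0.9)
  expect_gt(band_summary(spec, c(14, 20), "peak")$value,
            band_summary(spec, c(14, 20), "mean")$value)
  expect_true(band_summary(spec, c(14, 20))$significant)
  expect_error(band_summary(spec, c(200, 210)), class = "cmcgait_parameter_error")
})

test_that("median split labels high at or above the cohort median", {
  set.seed(5)
  v23 <- rnorm(23)
  g <- median_split(v23)
  expect_equal(as.vector(table(g)), c(12, 11))
  expect_true(all(v23[g == "high"] >= median(v23)))

  g4 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(g4), c("low", "low", "high", "high"))

  expect_message(gt <- median_split(c(1, 2, 2, 3)), "tie")
  expect_equal(as.character(gt), c("low", "high", "high", "high"))

  expect_error(median_split(c(1, 2, 3)), class = "cmcgait_parameter_error")
  expect_error(median_split(rep(0.5, 10)),
               class = "cmcgait_degenerate_split_error")
})

test_that("a calibrated shared-drive pair lands near its target coherence", {
  # generative model simulated directly, long run, many segments so the
  # estimator bias is negligible
  set.seed(6)
  target <- 0.26
  s2 <- 1 / sqrt(target) - 1
  expect_equal(s2, 0.9612, tolerance = 1e-3)
  bf <- signal::butter(4, c(14, 20) / 500, type = "pass")
  gen <- function() {
    z <- as.numeric(signal::filtfilt(bf, rnorm(510000)))
    z / sd(z)
  }
  s <- gen(); ex <- gen(); ey <- gen()
  x <- s + sqrt(s2) * ex
  y <- s + sqrt(s2) * ey
  L <- 3000
  nseg <- 170
  xm <- matrix(x[seq_len(L * nseg)], nrow = nseg, byrow = TRUE)
  ym <- matrix(y[seq_len(L * nseg)], nrow = nseg, byrow = TRUE)
  spec <- estimate_msc(xm, ym, rate = 1000)
  sel <- spec$freq >= 15 & spec$freq <= 19
  expect_equal(mean(spec$msc[sel]), target, tolerance = 0.04)
})
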