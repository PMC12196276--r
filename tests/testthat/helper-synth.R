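# Small configurations shared across test files. Kept deliberately tiny so
# signal-synthesis tests stay fast; full-size cohorts are exercised in the
# acceptance suite.

tiny_config <- function(...) {
  synth_config(n_high = 3, n_low = 3, trial_count = 3, seed = 42, ...)
}

# A clean trapezoidal test record: two channels of known content.
test_record <- function(n = 4000, rate = 1000) {
  t <- (0:(n - 1)) / rate
  signal_record(rbind(Cz = sin(2 * pi * 17 * t), TA = cos(2 * pi * 40 * t)),
                c("Cz", "TA"), rate = rate)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
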