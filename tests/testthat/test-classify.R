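# Bootstrap augmentation, SVM cross-validation, window sweep.

two_cluster_table <- function(n = 12, gap = 5, sd = 0.1, seed = 1) {
  set.seed(seed)
  data.frame(subject = sprintf("S%02d", 1:(2 * n)),
             window = "-500~0 ms",
             value = c(rnorm(n, -gap, sd), rnorm(n, gap, sd)),
             group = rep(c("high", "low"), each = n))
}

test_that("bootstrap augmentation resamples with replacement, deterministically", {
  tab <- two_cluster_table()
  aug <- bootstrap_augment(tab, 1000, seed = 3)
  expect_equal(nrow(aug), 1000)
  expect_true(all(aug$value %in% tab$value))
  expect_identical(aug, bootstrap_augment(tab, 1000, seed = 3))
  expect_false(identical(aug, bootstrap_augment(tab, 1000, seed = 4)))

  # class proportions follow the binomial expectation
  tab2 <- two_cluster_table()[c(1:12, 13:23), ]   # 12 high, 11 low
  big <- bootstrap_augment(tab2, 10000, seed = 5)
  expect_equal(mean(big$group == "high"), 12 / 23, tolerance = 0.04)

  expect_error(bootstrap_augment(tab, 1), class = "cmcgait_parameter_error")
  one_class <- tab[tab$group == "high", ]
  expect_error(bootstrap_augment(one_class, 10),
               class = "cmcgait_class_coverage_error")
})

test_that("well-separated clusters are classified perfectly", {
  aug <- bootstrap_augment(two_cluster_table(), 400, seed = 7)
  res <- svm_crossval(aug, folds = 5, seed = 7)
  expect_equal(res$accuracy, 1.0)
  expect_equal(unname(res$by_class$high["f1"]), 1.0)
  expect_equal(unname(res$by_class$low["f1"]), 1.0)
})

test_that("F1 is the harmonic mean of precision and recall on every row", {
  tab <- two_cluster_table(gap = 0.3, sd = 1, seed = 9)
  rep <- window_sweep(tab, sizes = c(100, 200), folds = 5, seed = 9)
  for (i in seq_len(nrow(rep$results))) {
    r <- rep$results[i, ]
    for (cl in c("high", "low")) {
      p <- r[[paste0("precision_", cl)]]
      rc <- r[[paste0("recall_", cl)]]
      f <- r[[paste0("f1_", cl)]]
      if (!is.na(f)) expect_equal(f, 2 * p * rc / (p + rc), tolerance = 1e-9)
    }
  }
})

test_that("shuffled labels give chance-level accuracy under leak-free CV", {
  # the permutation null must be evaluated leak-free: with augment-then-split
  # the resampled duplicates shared across folds let the model memorize even
  # random labels (that optimism is exactly the leakage the faithful mode
  # reproduces, and is asserted separately below)
  set.seed(13)
  accs <- replicate(20, {
    tab <- two_cluster_table(gap = 0, sd = 1, seed = sample.int(1e6, 1))
    tab$group <- sample(tab$group)
    rep <- window_sweep(tab, sizes = 200, folds = 5, seed = sample.int(1e6, 1),
                        cv_mode = "leakfree", primary_size = 200)
    rep$primary$accuracy
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.2)
})

test_that("augment-then-split exceeds leak-free CV on weak separation", {
  set.seed(14)
  faithful <- numeric(6); leakfree <- numeric(6)
  for (i in 1:6) {
    tab <- data.frame(subject = sprintf("S%02d", 1:23), window = "w",
                      value = c(rnorm(12, 0, 1), rnorm(11, 0.8, 1)),
                      group = rep(c("high", "low"), c(12, 11)))
    f <- window_sweep(tab, sizes = 500, folds = 5, seed = i,
                      cv_mode = "faithful", primary_size = 500)
    l <- window_sweep(tab, sizes = 500, folds = 5, seed = i,
                      cv_mode = "leakfree", primary_size = 500)
    faithful[i] <- f$primary$accuracy
    leakfree[i] <- l$primary$accuracy
  }
  expect_gt(mean(faithful), mean(leakfree))
  expect_gt(mean(faithful) - mean(leakfree), 0.1)
})

test_that("window sweep reports one row per window and size", {
  cfg <- tiny_config()
  tab <- synth_feature_table(synth_config(seed = 4))
  prep_windows <- feature_windows()$window[1:5]
  sub <- tab[tab$window %in% prep_windows, ]
  rep <- window_sweep(sub, sizes = c(50, 100), folds = 5, seed = 2,
                      primary_size = 100)
  expect_equal(nrow(rep$results), 10)
  expect_equal(nrow(rep$primary), 5)
  expect_true(all(rep$results$accuracy >= 0 & rep$results$accuracy <= 1))
  # determinism of the full report
  rep2 <- window_sweep(sub, sizes = c(50, 100), folds = 5, seed = 2,
                       primary_size = 100)
  expect_identical(rep$results, rep2$results)
  expect_error(window_sweep(tab[0, ]), class = "cmcgait_input_error")
})

test_that("identical features cannot beat the majority class", {
  tab <- data.frame(subject = sprintf("S%02d", 1:23), window = "w",
                    value = rep(1.7, 23),
                    group = rep(c("high", "low"), c(12, 11)))
  aug <- bootstrap_augment(tab, 500, seed = 21)
  res <- svm_crossval(aug, folds = 5, seed = 21)
  maj <- max(table(aug$group)) / nrow(aug)
  expect_equal(res$accuracy, maj, tolerance = 0.05)
})
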