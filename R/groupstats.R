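# Two-group statistics: Shapiro-Wilk-gated t / Mann-Whitney comparisons and
# pooled-SD Cohen's d, plus closed-form helpers that work from printed
# summary statistics (mean, SD, n).

#' Normality-gated two-group comparison
#'
#' Tests each group for normality with the Shapiro-Wilk test; if both groups
#' pass at `alpha`, an independent two-sample t-test with pooled variance is
#' used, otherwise the Mann-Whitney U (Wilcoxon rank-sum) test. Cohen's d
#' with pooled SD is always computed, signed as
#' (mean(high) - mean(low)) / SD_pooled.
#'
#' @param values_high,values_low numeric samples (n >= 3 each).
#' @param alpha significance level for both the normality gate and the group
#'   test (default 0.05).
#' @param metric optional metric name carried into the result.
#' @return Object of class `group_comparison`: list with `metric`, `test`
#'   (`"t"` or `"mann-whitney"`), `statistic`, `p_value`, `effect_size_d`,
#'   `significant`, `shapiro_p` (length-2), group `means`, `sds`, `ns`.
#' @export
compare_groups <- function(values_high, values_low, alpha = 0.05,
                           metric = NA_character_) {
  if (length(values_high) < 3 || length(values_low) < 3)
    stop_cmc("each group needs n >= 3", class = "cmcgait_parameter_error")
  m <- c(high = mean(values_high), low = mean(values_low))
  s <- c(high = stats::sd(values_high), low = stats::sd(values_low))
  n <- c(high = length(values_high), low = length(values_low))
  if (s["high"] == 0 && s["low"] == 0 && m["high"] == m["low"])
    stop_cmc("zero variance in both groups with equal means; d undefined",
             class = "cmcgait_undefined_d_error")
  sw <- c(high = tryCatch(stats::shapiro.test(values_high)$p.value, error = function(e) 0),
          low = tryCatch(stats::shapiro.test(values_low)$p.value, error = function(e) 0))
  normal <- all(sw > alpha)
  if (normal) {
    ht <- stats::t.test(values_high, values_low, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_high, values_low, exact = FALSE))
    test <- "mann-whitney"
  }
  d <- cohens_d_from_summary(m["high"], s["high"], n["high"],
                             m["low"], s["low"], n["low"])
  structure(list(metric = metric, test = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 effect_size_d = unname(d), significant = ht$p.value < alpha,
                 shapiro_p = sw, means = m, sds = s, ns = n, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s test: stat = %.3f, p = %.4g, d = %.2f (high %0.3f+/-%0.3f vs low %0.3f+/-%0.3f)\n",
              if (is.na(x$metric)) "" else paste0(" ", x$metric), x$test,
              x$statistic, x$p_value, x$effect_size_d,
              x$means["high"], x$sds["high"], x$means["low"], x$sds["low"]))
  invisible(x)
}

#' Cohen's d from summary statistics (pooled SD)
#'
#' \deqn{d = (m_1 - m_2) / \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return Cohen's d.
#' @examples
#' cohens_d_from_summary(34.26, 9.25, 12, 25.36, 9.43, 11)  # ~0.95
#' @export
cohens_d_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Pooled two-sample t-test from summary statistics
#'
#' Closed-form independent t-test with pooled variance and
#' df = n1 + n2 - 2; two-sided p-value.
#'
#' @inheritParams cohens_d_from_summary
#' @return Named vector `c(t, df, p)`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  p <- if (se == 0 && mean1 == mean2) 1 else 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}
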