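# Classifier: bootstrap augmentation, per-window RBF-SVM with stratified
# 5-fold cross-validation, and the window-by-bootstrap-size report.
#
# Two cross-validation orderings are exposed:
#   * "faithful": bootstrap-augment first, then split the augmented rows into
#     folds. Resampled duplicates are then shared between training and test
#     folds; this is the ordering that reproduces reported augmented-CV
#     accuracies, and the report always names the mode used.
#   * "leakfree": split the original subjects into folds, augment the
#     training subjects only, and test on the untouched held-out subjects.

#' Bootstrap augmentation of a feature table
#'
#' Draws `size` rows uniformly with replacement (labels carried along).
#' Deterministic given `seed`.
#'
#' @param table data.frame with at least columns `value` and `group` (both
#'   classes must be present, >= 2 rows per class).
#' @param size number of augmented rows (>= 2).
#' @param seed integer seed (optional).
#' @return data.frame of `size` resampled rows.
#' @export
bootstrap_augment <- function(table, size, seed = NULL) {
  if (size < 2)
    stop_cmc("size must be >= 2", class = "cmcgait_parameter_error")
  tab <- table(factor(table$group))
  if (length(tab) < 2 || any(tab < 2))
    stop_cmc("both classes need >= 2 rows (got: %s)",
             paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
             class = "cmcgait_class_coverage_error")
  idx <- with_seed(seed, sample.int(nrow(table), size, replace = TRUE))
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

classification_metrics <- function(truth, pred, classes = c("high", "low")) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  acc <- mean(pred == truth)
  per_class <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
          else 2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1)
  })
  names(per_class) <- classes
  list(accuracy = acc, by_class = per_class)
}

# RBF kernel width: quantile heuristic. gamma = 1 / q10(pairwise squared
# distances), computed on (a subsample of) the training fold. On
# bootstrap-duplicated data the low quantile shrinks towards the replicated
# point masses, so the kernel resolves individual resampled subjects.
gamma_heuristic <- function(x, q = 0.1, max_n = 300L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) > max_n) {
    keep <- with_seed(seed, sample.int(nrow(x), max_n))
    x <- x[keep, , drop = FALSE]
  }
  d2 <- as.vector(stats::dist(x))^2
  d2 <- d2[is.finite(d2)]
  if (!length(d2)) return(1)
  qv <- stats::quantile(d2, q, names = FALSE)
  if (qv <= 0) {
    pos <- d2[d2 > 0]
    if (!length(pos)) return(1)
    qv <- min(pos)
  }
  1 / qv
}

stratified_folds <- function(groups, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(groups))
    for (cl in unique(groups)) {
      w <- which(groups == cl)
      fold[w] <- sample(rep(seq_len(k), length.out = length(w)))
    }
    fold
  })
}

#' Cross-validated SVM on (augmented) feature rows
#'
#' Stratified k-fold cross-validation of a radial-basis support-vector
#' machine on the given rows. Features are z-scored using training-fold
#' statistics; the kernel width defaults to the quantile heuristic
#' (`gamma = NULL`), the cost to 1. Metrics are pooled over the held-out
#' predictions of all folds. If a fold ends up with a single class the data
#' are refolded with a new seed (error after 3 attempts).
#'
#' @param rows data.frame with columns `value` (numeric feature) and `group`
#'   (`"high"`/`"low"`).
#' @param folds number of folds (default 5, >= 2).
#' @param seed integer seed for fold assignment.
#' @param gamma RBF kernel width, or `NULL` for the quantile heuristic.
#' @param cost SVM regularization constant (default 1).
#' @return list with `accuracy`, `by_class` (precision/recall/F1 for high
#'   and low), `folds`, `n_rows`.
#' @export
svm_crossval <- function(rows, folds = 5, seed = NULL, gamma = NULL, cost = 1) {
  if (folds < 2)
    stop_cmc("folds must be >= 2", class = "cmcgait_parameter_error")
  groups <- factor(rows$group, levels = c("high", "low"))
  if (nlevels(droplevels(groups)) < 2)
    stop_cmc("both classes must be present", class = "cmcgait_class_coverage_error")
  for (attempt in 1:3) {
    fold <- stratified_folds(as.character(groups), folds,
                             seed = if (is.null(seed)) NULL else seed + attempt - 1L)
    ok <- all(vapply(seq_len(folds), function(k)
      nlevels(droplevels(groups[fold != k])) == 2, logical(1)))
    if (ok) break
    if (attempt == 3)
      stop_cmc("could not build folds with both classes after 3 attempts",
               class = "cmcgait_fold_error")
  }
  pred <- factor(rep(NA_character_, nrow(rows)), levels = levels(groups))
  for (k in seq_len(folds)) {
    tr <- fold != k
    mu <- mean(rows$value[tr]); sdv <- stats::sd(rows$value[tr])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    xtr <- matrix((rows$value[tr] - mu) / sdv)
    xte <- matrix((rows$value[!tr] - mu) / sdv)
    g <- gamma %||% gamma_heuristic(xtr)
    fit <- e1071::svm(x = xtr, y = droplevels(groups[tr]), kernel = "radial",
                      cost = cost, gamma = g, scale = FALSE)
    pred[!tr] <- factor(as.character(predict(fit, xte)), levels = levels(groups))
  }
  met <- classification_metrics(groups, pred)
  c(met, list(folds = folds, n_rows = nrow(rows)))
}

leakfree_crossval <- function(table, size, folds = 5, seed = NULL,
                              gamma = NULL, cost = 1) {
  groups <- factor(table$group, levels = c("high", "low"))
  fold <- stratified_folds(as.character(groups), folds, seed = seed)
  pred <- factor(rep(NA_character_, nrow(table)), levels = levels(groups))
  for (k in seq_len(folds)) {
    tr_rows <- table[fold != k, , drop = FALSE]
    aug <- bootstrap_augment(tr_rows, size,
                             seed = if (is.null(seed)) NULL else seed + 31L * k)
    mu <- mean(aug$value); sdv <- stats::sd(aug$value)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    xtr <- matrix((aug$value - mu) / sdv)
    xte <- matrix((table$value[fold == k] - mu) / sdv)
    g <- gamma %||% gamma_heuristic(xtr)
    fit <- e1071::svm(x = xtr, y = factor(aug$group, levels = levels(groups)),
                      kernel = "radial", cost = cost, gamma = g, scale = FALSE)
    pred[fold == k] <- factor(as.character(predict(fit, xte)), levels = levels(groups))
  }
  met <- classification_metrics(groups, pred)
  c(met, list(folds = folds, n_rows = nrow(table)))
}

#' Window-by-bootstrap-size classifier sweep
#'
#' For every feature window and every bootstrap size, augments the window's
#' subject rows and runs the cross-validated SVM, producing one report row
#' per (window, size). The headline summary uses `primary_size` (default
#' 1000, the sweep's maximum).
#'
#' @param table long feature table with columns `subject`, `window`, `value`,
#'   `group`.
#' @param sizes bootstrap sizes (default `c(10, seq(100, 1000, by = 100))`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed.
#' @param cv_mode `"faithful"` (augment then split; default) or `"leakfree"`
#'   (augment within training folds only).
#' @param gamma,cost SVM parameters, see [svm_crossval()].
#' @param primary_size bootstrap size of the headline summary (default 1000).
#' @return Object of class `classifier_report`: list with `results`
#'   (data.frame: window, size, accuracy, precision/recall/F1 per class),
#'   `primary` (rows at `primary_size`), `cv_mode`, `folds`, `seed`.
#' @export
window_sweep <- function(table, sizes = c(10, seq(100, 1000, by = 100)),
                         folds = 5, seed = 1L,
                         cv_mode = c("faithful", "leakfree"),
                         gamma = NULL, cost = 1, primary_size = 1000) {
  cv_mode <- match.arg(cv_mode)
  if (nrow(table) == 0)
    stop_cmc("empty feature table", class = "cmcgait_input_error")
  windows <- unique(table$window)
  rows <- list()
  for (w in windows) {
    wt <- table[table$window == w, , drop = FALSE]
    for (sz in sizes) {
      sub_seed <- substream_seed(seed, match(w, windows), stream = sz)
      res <- if (cv_mode == "faithful") {
        aug <- bootstrap_augment(wt, sz, seed = sub_seed)
        svm_crossval(aug, folds = folds, seed = sub_seed + 1L,
                     gamma = gamma, cost = cost)
      } else {
        leakfree_crossval(wt, sz, folds = folds, seed = sub_seed,
                          gamma = gamma, cost = cost)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        window = w, size = sz, accuracy = res$accuracy,
        precision_high = res$by_class$high["precision"],
        recall_high = res$by_class$high["recall"],
        f1_high = res$by_class$high["f1"],
        precision_low = res$by_class$low["precision"],
        recall_low = res$by_class$low["recall"],
        f1_low = res$by_class$low["f1"],
        row.names = NULL)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 primary = results[results$size == primary_size, , drop = FALSE],
                 cv_mode = cv_mode, folds = folds, seed = seed,
                 sizes = sizes, primary_size = primary_size),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> cv_mode = %s, %d-fold, primary bootstrap size %d\n",
              x$cv_mode, x$folds, x$primary_size))
  print(x$primary, row.names = FALSE, digits = 3)
  invisible(x)
}
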