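#' Confusion counts for a one-vs-rest class
#'
#' @param TP,TN True positive / true negative counts.
#' @param P,N Real positive / real negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, P, N) {
  vals <- c(TP = TP, TN = TN, P = P, N = N)
  if (any(vals < 0)) stop_invalid("counts must be non-negative")
  if (TP > P) stop_invalid("TP cannot exceed P")
  if (TN > N) stop_invalid("TN cannot exceed N")
  structure(as.list(vals), class = "confusion_counts")
}

#' Specificity, sensitivity and accuracy from confusion counts
#'
#' The three headline metrics, as percentages:
#' `specificity = 100 TN / N`, `sensitivity = 100 TP / P`,
#' `accuracy = 100 (TP + TN) / (P + N)`.
#'
#' @param counts A [confusion_counts()] (or a list with TP, TN, P, N).
#' @return A named numeric vector `c(specificity, sensitivity, accuracy)`.
#' @examples
#' metrics(confusion_counts(TP = 997, TN = 991, P = 1000, N = 1000))
#' @export
metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- do.call(confusion_counts, counts[c("TP", "TN", "P", "N")])
  }
  if (counts$P == 0 || counts$N == 0) {
    stop(errorCondition("metrics undefined when P or N is zero",
                        class = c("distecg_undefined_metric", "error")))
  }
  c(specificity = 100 * counts$TN / counts$N,
    sensitivity = 100 * counts$TP / counts$P,
    accuracy = 100 * (counts$TP + counts$TN) / (counts$P + counts$N))
}

#' Overall metric report from predictions
#'
#' Builds per-class one-vs-rest confusion counts, then reports the overall
#' specificity and sensitivity as macro averages over classes and the
#' overall accuracy as the pooled (plain classification) accuracy -- the
#' standard aggregation for imbalanced multi-class problems.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class label set; defaults to the sorted union of `y_true`.
#' @return An object of class `metric_report`: a list with `overall`
#'   (specificity/sensitivity/accuracy, percent), `per_class` (data frame),
#'   and `n`.
#' @export
overall_report <- function(y_true, y_pred, classes = sort(unique(y_true))) {
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  if (!all(y_pred %in% classes)) stop_invalid("prediction outside class set")
  if (!all(y_true %in% classes)) stop_invalid("true label outside class set")
  per <- lapply(classes, function(cl) {
    P <- sum(y_true == cl); N <- sum(y_true != cl)
    TP <- sum(y_true == cl & y_pred == cl)
    TN <- sum(y_true != cl & y_pred != cl)
    data.frame(class = cl, TP = TP, TN = TN, P = P, N = N,
               specificity = if (N > 0) 100 * TN / N else NA_real_,
               sensitivity = if (P > 0) 100 * TP / P else NA_real_)
  })
  per <- do.call(rbind, per)
  structure(list(
    overall = c(specificity = mean(per$specificity, na.rm = TRUE),
                sensitivity = mean(per$sensitivity, na.rm = TRUE),
                accuracy = 100 * mean(y_true == y_pred)),
    per_class = per, n = length(y_true)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  spec=%.1f  sens=%.1f  acc=%.1f (%%)\n",
              x$n, x$overall["specificity"], x$overall["sensitivity"],
              x$overall["accuracy"]))
  invisible(x)
}

#' Percentage improvement of a metric over a baseline
#'
#' `100 (new - base) / base`, reported to 3 significant figures (the display
#' precision used for improvement figures throughout the package).
#'
#' @param new_value,base_value Metric values; `base_value` must be positive.
#' @return Percentage improvement, rounded to 3 significant figures.
#' @examples
#' percentage_improvement(96.9, 93.3) # 3.86
#' percentage_improvement(47.5, 18.8) # 153
#' @export
percentage_improvement <- function(new_value, base_value) {
  if (any(base_value <= 0)) stop_invalid("base_value must be positive")
  signif(100 * (new_value - base_value) / base_value, 3)
}

#' k-fold cross-validation split
#'
#' Deterministic per seed; stratified by label when `labels` is given, so
#' each class's fold counts differ by at most one sample.
#'
#' @param n Sample count (`n >= k`).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @param labels Optional label vector of length `n` for stratification.
#' @return An object of class `fold_assignment`: list with `folds` (list of
#'   k index vectors, disjoint, union `1:n`), `k`, `seed`.
#' @export
kfold_split <- function(n, k = 5, seed = 1, labels = NULL) {
  if (n < k) stop_invalid("n must be at least k")
  if (!is.null(labels) && length(labels) != n) stop_invalid("labels length != n")
  with_seed(seed, {
    fold_of <- integer(n)
    if (is.null(labels)) {
      fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
    } else {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold_of[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    }
    folds <- lapply(seq_len(k), function(f) which(fold_of == f))
    structure(list(folds = folds, k = k, seed = seed),
              class = "fold_assignment")
  })
}

#' Per-class imbalance ratios
#'
#' Majority class size divided by each class size; sorting the result in
#' decreasing order identifies the most imbalanced classes.
#'
#' @param class_sizes Positive class-size vector (names preserved).
#' @return Numeric vector of ratios (majority class has ratio 1).
#' @examples
#' imbalance_ratio(c(class0 = 75052, class14 = 16))
#' @export
imbalance_ratio <- function(class_sizes) {
  if (any(class_sizes <= 0)) stop_invalid("class sizes must be positive")
  max(class_sizes) / class_sizes
}
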