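test_that("metrics reproduce the headline worked example", {
  m <- metrics(confusion_counts(TP = 997, TN = 991, P = 1000, N = 1000))
  expect_equal(unname(m["specificity"]), 99.1)
  expect_equal(unname(m["sensitivity"]), 99.7)
  expect_equal(unname(m["accuracy"]), 99.4)
})

test_that("metrics are bounded and satisfy the accuracy identity", {
  set.seed(1)
  for (i in 1:20) {
    P <- sample(1:50, 1); N <- sample(1:50, 1)
    cc <- confusion_counts(TP = sample(0:P, 1), TN = sample(0:N, 1),
                           P = P, N = N)
    m <- metrics(cc)
    expect_true(all(m >= 0 & m <= 100))
    expect_equal(unname(m["accuracy"]),
                 100 * (cc$TP + cc$TN) / (P + N), tolerance = 1e-9)
  }
  expect_error(metrics(confusion_counts(TP = 0, TN = 2, P = 0, N = 2)),
               class = "distecg_undefined_metric")
})

test_that("overall_report macro-averages and pools correctly", {
  ## hand-computed 3-class example
  y_true <- c(0, 0, 0, 1, 1, 2)
  y_pred <- c(0, 0, 1, 1, 1, 0)
  r <- overall_report(y_true, y_pred, classes = 0:2)
  expect_equal(unname(r$overall["accuracy"]), 100 * 4 / 6)
  sens <- c(2 / 3, 2 / 2, 0 / 1) * 100
  spec <- c(2 / 3, 3 / 4, 5 / 5) * 100
  expect_equal(unname(r$overall["sensitivity"]), mean(sens))
  expect_equal(unname(r$overall["specificity"]), mean(spec))
  ## all correct -> every metric 100
  p <- overall_report(y_true, y_true, classes = 0:2)
  expect_equal(unname(p$overall), c(100, 100, 100))
  ## binary case agrees with metrics() of the positive class
  yt <- c(1, 1, 1, 0, 0); yp <- c(1, 1, 0, 0, 1)
  rb <- overall_report(yt, yp, classes = 0:1)
  mb <- metrics(confusion_counts(TP = 2, TN = 1, P = 3, N = 2))
  expect_equal(unname(rb$per_class$sensitivity[rb$per_class$class == 1]),
               unname(mb["sensitivity"]))
  expect_error(overall_report(c(0, 1), c(0, 2), classes = 0:1),
               class = "distecg_invalid_argument")
})

test_that("percentage improvement reproduces the cross-checked figures", {
  expect_equal(percentage_improvement(96.6, 92.8), 4.09)
  expect_equal(percentage_improvement(97.2, 93.7), 3.74)
  expect_equal(percentage_improvement(96.9, 93.3), 3.86)
  expect_equal(percentage_improvement(47.5, 18.8), 153)
  expect_equal(percentage_improvement(55, 55), 0)
  expect_error(percentage_improvement(1, 0),
               class = "distecg_invalid_argument")
})

test_that("k-fold splits are exact, stratified and seeded", {
  f <- kfold_split(100, k = 5, seed = 1)
  sizes <- vapply(f$folds, length, integer(1))
  expect_identical(sizes, rep(20L, 5))
  expect_identical(sort(unlist(f$folds)), 1:100)
  ## stratified 90/10: each fold within +/- 1 sample of 10% minority
  labels <- rep(c(0, 1), c(90, 10))
  fs <- kfold_split(100, k = 5, seed = 2, labels = labels)
  minority <- vapply(fs$folds, function(ix) sum(labels[ix] == 1), integer(1))
  expect_true(all(abs(minority - 2) <= 1))
  expect_identical(kfold_split(60, k = 4, seed = 7),
                   kfold_split(60, k = 4, seed = 7))
  expect_error(kfold_split(3, k = 5), class = "distecg_invalid_argument")
})

test_that("imbalance ratios follow the majority-over-size rule", {
  r <- imbalance_ratio(c(a = 75052, b = 16))
  expect_equal(unname(r["b"]), 4690.75)
  expect_equal(unname(r["a"]), 1)
  expect_equal(unname(imbalance_ratio(c(5, 5, 5))), rep(1, 3))
  ## scale invariance
  s <- c(40, 10, 4)
  expect_equal(imbalance_ratio(s * 7), imbalance_ratio(s))
  expect_error(imbalance_ratio(c(5, 0)), class = "distecg_invalid_argument")
})
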