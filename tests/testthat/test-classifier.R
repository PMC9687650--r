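test_that("the backbone has ten layers with exact shape arithmetic", {
  cnn <- build_cnn(360, 5)
  expect_length(cnn$spec, 10)
  kinds <- vapply(cnn$spec, `[[`, character(1), "kind")
  expect_identical(kinds, c("conv1d", "batchnorm", "maxpool", "conv1d",
                            "batchnorm", "maxpool", "conv1d", "conv1d",
                            "dense", "output"))
  ## valid padding + floor division, checked stage by stage for length 360
  lens <- vapply(cnn$shapes, `[[`, numeric(1), "len")
  expect_equal(lens[1], 360)                    # input
  expect_equal(lens[2], (360 - 50) %/% 3 + 1)   # conv 50/3 -> 104
  expect_equal(lens[4], (104 - 2) %/% 3 + 1)    # pool 2/3 -> 35
  expect_equal(lens[5], (35 - 8) %/% 1 + 1)     # conv 8 -> 28
  expect_equal(lens[7], (28 - 2) %/% 2 + 1)     # pool 2/2 -> 14
  expect_equal(lens[8], 14 - 5 + 1)             # conv 5 -> 10
  expect_equal(lens[9], 10 - 3 + 1)             # conv 3 -> 8
  expect_equal(lens[10], 64)                    # dense
  expect_equal(lens[11], 5)                     # softmax output
})

test_that("build_cnn rejects invalid geometry", {
  expect_error(build_cnn(40, 2), class = "distecg_invalid_argument")
  expect_error(build_cnn(100, 2), class = "distecg_invalid_argument")
  expect_error(build_cnn(360, 1), class = "distecg_invalid_argument")
})

test_that("parameter count is a pure function of the architecture", {
  a <- build_cnn(240, 2)
  b <- build_cnn(240, 2)
  expect_identical(cnn_parameter_count(a), cnn_parameter_count(b))
  expect_gt(cnn_parameter_count(a), 1e5)
  ## wider head means more parameters
  expect_gt(cnn_parameter_count(build_cnn(240, 2, dense_units = 128)),
            cnn_parameter_count(a))
})

test_that("predictions are proper probability rows", {
  cnn <- build_cnn(240, 3)
  x <- matrix(rnorm(5 * 240), 5, 240)
  p <- predict(cnn, x)
  expect_equal(dim(p$probs), c(5, 3))
  expect_equal(rowSums(p$probs), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p$labels %in% 0:2))
  expect_error(predict(cnn, matrix(0, 2, 100)),
               class = "distecg_invalid_argument")
})

test_that("training separates a two-frequency toy problem", {
  d <- separable_beats()
  cnn <- build_cnn(240, 2)
  tr <- train_classifier(cnn, d$x, d$y,
                         classifier_config(epochs = 5, batch = 16, seed = 1))
  expect_length(tr$loss_curve, 5)
  expect_lt(tail(tr$loss_curve, 1), tr$loss_curve[1])
  expect_gte(mean(predict(tr, d$x)$labels == d$y), 0.95)
})

test_that("classifier training is deterministic and epochs = 0 is identity", {
  d <- separable_beats(n = 20)
  cnn <- build_cnn(240, 2)
  cfg <- classifier_config(epochs = 2, batch = 8, seed = 4)
  expect_identical(train_classifier(cnn, d$x, d$y, cfg)$model,
                   train_classifier(cnn, d$x, d$y, cfg)$model)
  same <- train_classifier(cnn, d$x, d$y, classifier_config(epochs = 0))
  expect_identical(same$model, cnn$model)
  expect_warning(train_classifier(cnn, d$x[d$y == 0, ], d$y[d$y == 0],
                                  classifier_config(epochs = 1)),
                 "degenerate")
})

test_that("resample_beat maps onto the requested grid", {
  x <- sin(seq(0, 2 * pi, length.out = 100))
  y <- resample_beat(x, 360)
  expect_length(y, 360)
  expect_equal(y[1], x[1])
  expect_equal(y[360], x[100])
  ## identity when the lengths already agree
  expect_equal(resample_beat(x, 100), x)
  expect_error(resample_beat(1), class = "distecg_invalid_argument")
})

test_that("engine gradients agree with central finite differences", {
  ns <- asNamespace("distecg")
  set.seed(9)
  len_out <- ((((20 - 4) %/% 2 + 1 - 2) %/% 2 + 1 - 3) %/% 1 + 1)
  model <- ns$nn_init(list(
    ns$nn_conv1d(4, 1, 3, 2, "relu"),
    ns$nn_batchnorm(3),
    ns$nn_maxpool(2, 2),
    ns$nn_conv1d(3, 3, 2, 1, "relu"),
    ns$nn_flatten(),
    ns$nn_dense(2 * len_out, 5, "tanh"),
    ns$nn_dense(5, 3, "softmax")))
  x <- array(rnorm(4 * 20), c(4, 20, 1))
  y <- ns$one_hot(c(0, 1, 2, 1), 3)
  lossfun <- function(m) {
    ns$ce_loss(ns$nn_forward(m, x, train = TRUE)$out, y)$loss
  }
  fw <- ns$nn_forward(model, x, train = TRUE)
  bw <- ns$nn_backward(fw$model, fw$caches, ns$ce_loss(fw$out, y)$dprobs)
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(model$layers)) {
    for (p in ns$nn_param_names(model$layers[[i]])) {
      th <- model$layers[[i]][[p]]
      for (j in sample(length(th), min(4, length(th)))) {
        m1 <- model; m1$layers[[i]][[p]][j] <- th[j] + eps
        m2 <- model; m2$layers[[i]][[p]][j] <- th[j] - eps
        num <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
        ana <- bw$grads[[i]][[p]][j]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-6)
})
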