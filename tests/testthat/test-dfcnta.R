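test_that("virtual labeling reserves one extra label outside the class set", {
  v <- virtual_labeling(0:4)
  expect_identical(v$y_v, 5L)
  expect_false(v$y_v %in% v$classes)
  v2 <- virtual_labeling(c(2, 0, 1))
  expect_identical(v2$y_v, 3L)
})

test_that("assign_virtual_labels pairs every unlabeled sample with y_v", {
  v <- virtual_labeling(0:1)
  out <- assign_virtual_labels(matrix(0, 5, 3), v)
  expect_length(out$y, 5)
  expect_true(all(out$y == v$y_v))
  empty <- assign_virtual_labels(matrix(0, 0, 3), v)
  expect_length(empty$y, 0)
})

test_that("gan_loss hits the closed form and a brute-force oracle", {
  b <- transfer_batch(x_s = matrix(1:2, 2, 1), y_s = c(0, 1),
                      x_l = matrix(3:4, 2, 1), y_l = c(0, 1),
                      x_u = matrix(5:6, 2, 1))
  v <- virtual_labeling(0:1)
  half <- function(f, y) rep(0.5, nrow(f))
  expect_equal(gan_loss(identity, half, b, v), 4 * log(0.5))

  ## non-trivial feature/disc functions against a scalar hand computation
  feat <- function(x) x * 2
  disc <- function(f, y) 1 / (1 + exp(-(0.3 * rowSums(f) - 0.1 * y)))
  got <- gan_loss(feat, disc, b, v)
  by_hand <- function(x, y, flip) {
    s <- vapply(seq_along(y), function(i) disc(feat(x)[i, , drop = FALSE], y[i]),
                numeric(1))
    if (flip) mean(log(1 - s)) else mean(log(s))
  }
  want <- by_hand(b$x_u, rep(v$y_v, 2), FALSE) +
    by_hand(b$x_s, rep(v$y_v, 2), TRUE) +
    by_hand(b$x_l, b$y_l, FALSE) +
    by_hand(b$x_s, b$y_s, TRUE)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("empty batch parts contribute zero to gan_loss", {
  b <- transfer_batch(x_l = matrix(0, 2, 1), y_l = c(0, 1))
  v <- virtual_labeling(0:1)
  half <- function(f, y) rep(0.5, nrow(f))
  expect_message(got <- gan_loss(identity, half, b, v))
  expect_equal(got, log(0.5))  # only the labeled-target term survives
})

test_that("term switches drop the corresponding gan_loss parts", {
  b <- transfer_batch(x_s = matrix(1:2, 2, 1), y_s = c(0, 1),
                      x_l = matrix(3:4, 2, 1), y_l = c(0, 1),
                      x_u = matrix(5:6, 2, 1))
  v <- virtual_labeling(0:1)
  half <- function(f, y) rep(0.5, nrow(f))
  expect_equal(gan_loss(identity, half, b, v,
                        terms = list(domain = FALSE, joint = TRUE)),
               2 * log(0.5))
  expect_equal(gan_loss(identity, half, b, v,
                        terms = list(domain = TRUE, joint = FALSE)),
               2 * log(0.5))
})

test_that("weighted_class_loss matches a scalar oracle and is non-negative", {
  cls <- function(f) {
    z <- cbind(f[, 1], -f[, 1])
    exp(z) / rowSums(exp(z))
  }
  b <- transfer_batch(x_s = matrix(c(0.5, -0.2, 0.1), 3, 1), y_s = c(0, 1, 0),
                      x_l = matrix(c(1, -1), 2, 1), y_l = c(0, 1))
  h <- transfer_hyper(phi = c(1, 0.5, 2), gamma_scale = 0.7)
  got <- weighted_class_loss(identity, cls, b, h, n_classes = 2)
  p_l <- cls(b$x_l); p_s <- cls(b$x_s)
  ce_l <- -log(p_l[cbind(1:2, b$y_l + 1)])
  ce_s <- -log(p_s[cbind(1:3, b$y_s + 1)])
  expect_equal(got, mean(ce_l) + 0.7 * mean(c(1, 0.5, 2) * ce_s),
               tolerance = 1e-6)
  expect_gte(got, 0)
  ## scalar phi broadcasts; wrong length errors
  expect_silent(weighted_class_loss(identity, cls, b,
                                    transfer_hyper(phi = 1), n_classes = 2))
  expect_error(weighted_class_loss(identity, cls, b,
                                   transfer_hyper(phi = c(1, 2)),
                                   n_classes = 2),
               class = "distecg_invalid_argument")
})

test_that("weighted_class_loss is ~0 iff certain and correct", {
  sure <- function(f) matrix(rep(c(1, 0), each = 2), 2, 2)
  b <- transfer_batch(x_l = matrix(0, 2, 1), y_l = c(0, 0))
  got <- weighted_class_loss(identity, sure, b, transfer_hyper())
  expect_lt(got, 1e-6)
})

test_that("the min-max objective follows its arithmetic", {
  expect_equal(dfcnta_objective(1.0, -2.0, 0.5), 2.0)
  expect_equal(dfcnta_objective(1.3, -2.0, 0), 1.3)  # sigma = 0: unchanged
  ## monotone decreasing in gan_loss for sigma > 0
  g <- seq(-3, 0, by = 0.5)
  obj <- vapply(g, function(gl) dfcnta_objective(1, gl, 0.5), numeric(1))
  expect_true(all(diff(obj) < 0))
  expect_error(dfcnta_objective(Inf, 0, 0.1),
               class = "distecg_invalid_argument")
})

test_that("train_transfer_stage produces a full per-round trace", {
  set.seed(1)
  st <- train_transfer_stage(
    target_data = list(x_l = matrix(rnorm(40), 20, 2),
                       y_l = rep(0:1, each = 10)),
    schedule = transfer_schedule(rounds = 10, seed = 2))
  expect_identical(dim(st$trace), c(10L, 3L))
  expect_identical(colnames(st$trace),
                   c("class_loss", "gan_loss", "objective"))
  expect_true(all(is.finite(st$trace)))
})

test_that("sigma = 0, gamma = 0 reduces exactly to target-only training", {
  set.seed(3)
  tgt <- list(x_l = matrix(rnorm(60), 30, 2), y_l = rep(0:2, 10))
  src <- list(x = matrix(rnorm(80, 2), 40, 2), y = rep(0:2, length.out = 40))
  sched <- transfer_schedule(rounds = 25, seed = 9)
  with_src <- train_transfer_stage(
    source_data = src, target_data = tgt,
    hyper = transfer_hyper(gamma_scale = 0, sigma_adv = 0),
    schedule = sched, n_classes = 3)
  without_src <- train_transfer_stage(
    source_data = NULL, target_data = tgt,
    hyper = transfer_hyper(gamma_scale = 0, sigma_adv = 0),
    schedule = sched, n_classes = 3)
  expect_identical(with_src$feature, without_src$feature)
  expect_identical(with_src$classifier, without_src$classifier)
})

test_that("phi grid search down-weights an adversarial source", {
  set.seed(4)
  x_t <- rbind(matrix(rnorm(40, 2, 0.5), 20, 2),
               matrix(rnorm(40, -2, 0.5), 20, 2))
  y_t <- rep(0:1, each = 20)
  ## source with deliberately flipped labels: pure negative transfer
  x_s <- rbind(matrix(rnorm(80, 2, 0.5), 40, 2),
               matrix(rnorm(80, -2, 0.5), 40, 2))
  y_s <- rep(1:0, each = 40)
  st <- train_transfer_stage(
    source_data = list(x = x_s, y = y_s),
    target_data = list(x_l = x_t, y_l = y_t),
    hyper = transfer_hyper(phi_mode = "grid"),
    schedule = transfer_schedule(rounds = 40, seed = 5), n_classes = 2)
  expect_identical(st$phi_selected, 0)
  acc <- mean(predict(st, x_t)$labels == y_t)
  expect_gte(acc, 0.95)
})

test_that("transfer stage training is deterministic", {
  set.seed(8)
  tgt <- list(x_l = matrix(rnorm(40), 20, 2), y_l = rep(0:1, 10))
  src <- list(x = matrix(rnorm(40, 1), 20, 2), y = rep(0:1, 10))
  a <- train_transfer_stage(source_data = src, target_data = tgt,
                            schedule = transfer_schedule(rounds = 15, seed = 3))
  b <- train_transfer_stage(source_data = src, target_data = tgt,
                            schedule = transfer_schedule(rounds = 15, seed = 3))
  expect_identical(a, b)
})
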