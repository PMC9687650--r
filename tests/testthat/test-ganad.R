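test_that("logistic_mixture validates its parameters", {
  expect_error(logistic_mixture(c(0.5, 0.6), matrix(0, 2, 1), matrix(1, 2, 1)),
               class = "distecg_invalid_argument")
  expect_error(logistic_mixture(1, matrix(0, 1, 1), matrix(-1, 1, 1)),
               class = "distecg_invalid_argument")
  expect_error(logistic_mixture(c(0.5, 0.5), matrix(0, 1, 1), matrix(1, 1, 1)),
               class = "distecg_invalid_argument")
  m <- logistic_mixture(c(0.3, 0.7), matrix(0, 2, 3), matrix(1, 2, 3))
  expect_identical(m$n_components, 2L)
  expect_identical(m$K, 3L)
})

test_that("sample_latent is shaped, seeded and component-faithful", {
  m <- logistic_mixture(c(0.2, 0.8), matrix(c(0, 10), 2, 2),
                        matrix(0.1, 2, 2))
  s1 <- sample_latent(m, 500, seed = 3)
  s2 <- sample_latent(m, 500, seed = 3)
  expect_identical(s1, s2)
  expect_equal(dim(s1$z), c(500, 2))
  ## a draw from component 2 must sit near gamma_2 = (10, 10)
  expect_true(all(abs(s1$z[s1$components == 2, 1] - 10) < 5))
  expect_true(all(abs(s1$z[s1$components == 1, 1]) < 5))
})

test_that("a zero-scale component is deterministic at its location", {
  m <- logistic_mixture(1, matrix(c(1, 2), 1), matrix(0, 1, 2))
  z <- sample_latent(m, 3)$z
  expect_equal(z, matrix(c(1, 2), 3, 2, byrow = TRUE))
})

test_that("gaussian noise ablation changes the draw distribution", {
  g1 <- logistic_mixture(1, matrix(0, 1, 1), matrix(1, 1, 1),
                         noise = "gaussian")
  z <- sample_latent(g1, 100000, seed = 1)$z
  k <- mean((z - mean(z))^4) / mean((z - mean(z))^2)^2 - 3
  expect_lt(abs(k), 0.1)  # normal excess kurtosis 0, not the logistic 1.2
})

test_that("discriminator loss matches its closed forms and bound", {
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(0.5))
  expect_equal(discriminator_loss(c(0.5, 0.5), 0.5), 2 * log(0.5))
  ## brute-force oracle on a batch of 3
  dr <- c(0.9, 0.8, 0.6); df <- c(0.2, 0.1, 0.3)
  expect_equal(discriminator_loss(dr, df),
               mean(log(dr)) + mean(log(1 - df)), tolerance = 1e-12)
  expect_lte(discriminator_loss(runif(5), runif(5)), 0)
})

test_that("generator regularizer is the weighted squared scale gap", {
  beta <- c(0.25, 0.75)
  theta <- matrix(c(1, 1, 0.5, 2), 2, 2, byrow = TRUE)
  expect_equal(generator_regularizer(beta, theta, 0.1),
               0.1 * (0.25 * 0 + 0.75 * (0.25 + 1)), tolerance = 1e-12)
  expect_identical(generator_regularizer(beta, matrix(1, 2, 2), 0.1), 0)
  expect_identical(generator_regularizer(beta, theta, 0), 0)
  expect_error(generator_regularizer(beta, theta, -1),
               class = "distecg_invalid_argument")
})

test_that("generator loss adds the regularizer to the adversarial part", {
  beta <- 1; theta <- matrix(2, 1, 1)
  expect_equal(generator_loss(0.5, beta, theta, 0.3),
               log(0.5) + 0.3 * 1, tolerance = 1e-12)
})

test_that("GAN training is deterministic with a complete loss trace", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 2, 0.3), 30, 2),
             matrix(rnorm(60, -2, 0.3), 30, 2))
  y <- rep(0:1, each = 30)
  cfg <- gan_config(epochs = 20, d_steps = 2, g_steps = 1, batch = 16,
                    seed = 7)
  g1 <- train_auxiliary_gan(x, y, stage = 1, config = cfg)
  g2 <- train_auxiliary_gan(x, y, stage = 1, config = cfg)
  expect_identical(g1, g2)
  expect_length(g1$loss_trace, 20 * (2 + 1))
  expect_true(all(is.finite(g1$loss_trace)))
  expect_s3_class(g1$mixture, "logistic_mixture")
  expect_true(all(g1$mixture$delta >= 0))
})

test_that("a trained GAN recovers conditional cluster means", {
  set.seed(5)
  n <- 120
  x <- rbind(matrix(rnorm(n, 3, 0.3), n / 2, 2),
             matrix(rnorm(n, -3, 0.3), n / 2, 2))
  y <- rep(0:1, each = n / 2)
  gan <- train_auxiliary_gan(x, y, stage = 1,
                             config = gan_config(epochs = 5000, batch = 30,
                                                 seed = 11))
  aux <- generate_auxiliary_domain(gan, c("0" = 200, "1" = 200), seed = 3)
  m0 <- colMeans(aux$x[aux$y == 0, , drop = FALSE])
  m1 <- colMeans(aux$x[aux$y == 1, , drop = FALSE])
  expect_lt(max(abs(m0 - 3)), 0.5)
  expect_lt(max(abs(m1 + 3)), 0.5)
})

test_that("auxiliary generation honors per-class counts exactly", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, 10)
  gan <- train_auxiliary_gan(x, y, stage = 2,
                             config = gan_config(epochs = 5, batch = 8,
                                                 seed = 2))
  aux <- generate_auxiliary_domain(gan, c("0" = 7, "1" = 3), seed = 4)
  expect_identical(unname(table(aux$y)["0"]), 7L)
  expect_identical(unname(table(aux$y)["1"]), 3L)
  expect_identical(aux$stage, 2)
  expect_error(generate_auxiliary_domain(gan, c("5" = 2), seed = 1),
               class = "distecg_invalid_argument")
  ## same seed, same draw
  expect_identical(aux, generate_auxiliary_domain(gan, c("0" = 7, "1" = 3),
                                                  seed = 4))
})
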