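test_that("synthetic ECG reports exact integer R locations", {
  out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 12, heart_rate = 75,
                                  seed = 1))
  r <- out$truth$r_locs
  expect_true(all(r == round(r)))
  expect_gte(r[1], 0.3 * 200)
  expect_true(all(diff(r) > 0))
  ## the R sample is a local maximum of the trace
  s <- out$signal$samples
  expect_true(all(s[r + 1] >= s[r]) && all(s[r + 1] >= s[r + 2]))
  ## deterministic
  expect_identical(out, synth_ecg(synth_ecg_spec(fs = 200, duration = 12,
                                                 heart_rate = 75, seed = 1)))
})

test_that("snr_db controls the white-noise level", {
  clean <- synth_ecg(synth_ecg_spec(duration = 10, seed = 2))
  noisy <- synth_ecg(synth_ecg_spec(duration = 10, seed = 2, snr_db = 20))
  noise <- noisy$signal$samples - clean$signal$samples
  snr <- 10 * log10(mean(clean$signal$samples^2) / mean(noise^2))
  expect_equal(snr, 20, tolerance = 0.5)
})

test_that("the QRS template concentrates energy in the 10-30 Hz band", {
  spec <- synth_ecg_spec()
  t <- seq(-0.1, 0.1, by = 1 / 200)
  tpl <- ecg_beat_template(spec, t, waves = c("Q", "R", "S"))
  n <- 1024
  amp <- abs(stats::fft(c(tpl, rep(0, n - length(tpl)))))[2:(n / 2)]
  freq <- (1:(n / 2 - 1)) * 200 / n
  peak <- freq[which.max(amp)]
  expect_gte(peak, 10)
  expect_lte(peak, 30)
})

test_that("domain class counts follow the priors by largest remainder", {
  sp <- synth_domain_spec(n = 10, n_classes = 3, priors = c(0.5, 0.3, 0.2),
                          seed = 1)
  d <- synth_domain(sp)
  expect_identical(as.integer(table(d$y)), c(5L, 3L, 2L))
  ## skewed priors at awkward n still sum exactly
  sp2 <- synth_domain_spec(n = 7, n_classes = 3, priors = c(0.6, 0.25, 0.15),
                           seed = 1)
  expect_identical(sum(table(synth_domain(sp2)$y)), 7L)
})

test_that("the paired target domain is the source shifted by a common delta", {
  sp <- synth_domain_spec(n = 3000, dim = 3, n_classes = 2, delta = 2,
                          cov_scale = 0.5, seed = 4)
  src <- synth_domain(sp)
  tgt <- synth_domain(sp, domain = "target")
  shift0 <- colMeans(tgt$x[tgt$y == 0, ]) - colMeans(src$x[src$y == 0, ])
  shift1 <- colMeans(tgt$x[tgt$y == 1, ]) - colMeans(src$x[src$y == 1, ])
  expect_equal(shift0, shift1, tolerance = 0.15)
  ## scalar delta is added to every coordinate of every class mean
  expect_equal(unname(shift0), rep(2, 3), tolerance = 0.15)
})

test_that("bayes accuracy is near 1 when classes are well separated", {
  easy <- synth_domain(synth_domain_spec(n = 100, dim = 2, n_classes = 2,
                                         class_sep = 6, cov_scale = 0.3,
                                         seed = 3))
  hard <- synth_domain(synth_domain_spec(n = 100, dim = 2, n_classes = 2,
                                         class_sep = 6, cov_scale = 9,
                                         seed = 3))
  a_easy <- bayes_accuracy(easy$truth)
  a_hard <- bayes_accuracy(hard$truth)
  expect_gte(a_easy, 0.95)
  expect_gt(a_easy, a_hard)
})

test_that("benchmark class sizes match the published skew", {
  s <- benchmark_class_sizes("mit-bih")
  expect_length(s, 15)
  expect_equal(unname(s[1]), 75052)
  expect_equal(unname(s[15]), 16)
  expect_equal(max(imbalance_ratio(s)), 4690.75)
  expect_length(benchmark_class_sizes("ptb-xl"), 5)
  expect_error(benchmark_class_sizes("nope"))
})

test_that("imbalanced beat sets honor requested class sizes", {
  sizes <- c(30, 8, 3)
  d <- synth_imbalanced_beats(sizes, beat_len = 120, seed = 5)
  expect_identical(as.integer(table(d$y)), c(30L, 8L, 3L))
  expect_identical(ncol(d$x), 120L)
  expect_identical(d, synth_imbalanced_beats(sizes, beat_len = 120, seed = 5))
})
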