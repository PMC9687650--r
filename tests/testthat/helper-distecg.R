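## Shared builders for the transfer-learning tests: a family of paired
## shifted domains (two sources + one label-scarce target per seed) and a
## small pipeline configuration sized for one CPU.

shifted_family <- function(seed, cov_scale = 1.5, n_source = 150,
                           n_target = 36, dim = 4, n_classes = 3,
                           delta = 0.8) {
  mk <- function(s, n, domain) {
    synth_domain(synth_domain_spec(n = n, dim = dim, n_classes = n_classes,
                                   delta = delta, cov_scale = cov_scale,
                                   seed = s),
                 domain = domain)
  }
  list(s1 = mk(seed * 10 + 1, n_source, "source"),
       s2 = mk(seed * 10 + 2, n_source, "source"),
       tg = mk(seed * 10 + 1, n_target, "target"))
}

small_pipeline_config <- function(..., gan_epochs = 1500, rounds = 60) {
  pipeline_config(gan = gan_config(epochs = gan_epochs, seed = 1),
                  schedule = transfer_schedule(rounds = rounds),
                  cv_k = 3, aux_n = 90, ...)
}

## two-frequency separable beat-like matrix for classifier tests
separable_beats <- function(n = 60, len = 240, seed = 2) {
  set.seed(seed)
  t <- seq(0, 1, length.out = len)
  x0 <- t(replicate(n / 2, sin(2 * pi * 3 * t) + stats::rnorm(len, 0, 0.1)))
  x1 <- t(replicate(n / 2, sin(2 * pi * 7 * t) + stats::rnorm(len, 0, 0.1)))
  list(x = rbind(x0, x1), y = rep(0:1, each = n / 2))
}
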