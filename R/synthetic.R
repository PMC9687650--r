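#' Specification for a synthetic ECG trace
#'
#' Parametric single-lead ECG model: each beat is a sum of Gaussian bumps
#' (P, Q, R, S, T) centered on exact R-peak sample times derived from the
#' heart rate, plus configurable powerline interference, baseline wander,
#' and white noise. The default QRS morphology is chosen so that the
#' template's discrete spectrum peaks inside the 10-30 Hz band typical of
#' QRS complexes.
#'
#' @param fs Sampling rate (Hz).
#' @param duration Trace length (s).
#' @param heart_rate Mean heart rate (bpm), in `[20, 240]`.
#' @param hr_jitter_sd SD of per-beat RR-interval jitter (s); 0 = metronomic.
#' @param wave_amp Named amplitudes (mV) of the P/Q/R/S/T bumps.
#' @param wave_width Named Gaussian widths (s) of the bumps.
#' @param wave_offset Named centers (s) of the bumps relative to R.
#' @param powerline_amp,powerline_hz Powerline interference amplitude (mV)
#'   and frequency (50 Hz default, mains in the European recordings these
#'   defaults emulate; set 60 for North American mains).
#' @param baseline_amp,baseline_hz Baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz).
#' @param white_sd White-noise SD (mV).
#' @param snr_db Optional signal-to-noise ratio in dB; when given it
#'   overrides `white_sd` so the white-noise power matches the clean-trace
#'   power at this SNR.
#' @param seed RNG seed making the trace a pure function of the spec.
#' @return A list of class `synth_ecg_spec`.
#' @export
synth_ecg_spec <- function(fs = 200, duration = 30, heart_rate = 60,
                           hr_jitter_sd = 0,
                           wave_amp = c(P = 0.15, Q = -0.2, R = 1.0,
                                        S = -0.3, T = 0.35),
                           wave_width = c(P = 0.04, Q = 0.013, R = 0.011,
                                          S = 0.014, T = 0.07),
                           wave_offset = c(P = -0.2, Q = -0.033, R = 0,
                                           S = 0.035, T = 0.3),
                           powerline_amp = 0, powerline_hz = 50,
                           baseline_amp = 0, baseline_hz = 0.3,
                           white_sd = 0, snr_db = NULL, seed = NULL) {
  if (fs <= 0 || duration <= 0) stop_invalid("fs and duration must be positive")
  if (heart_rate < 20 || heart_rate > 240) {
    stop_invalid("heart_rate must lie in [20, 240] bpm")
  }
  structure(as.list(environment()), class = "synth_ecg_spec")
}

#' Beat template of a synthetic ECG spec, sampled on a time grid
#'
#' @param spec A [synth_ecg_spec()].
#' @param t Time offsets (s) relative to the R peak.
#' @param waves Which bumps to include (default all five).
#' @return Numeric template values (mV).
#' @export
ecg_beat_template <- function(spec, t, waves = c("P", "Q", "R", "S", "T")) {
  stopifnot(inherits(spec, "synth_ecg_spec"))
  y <- numeric(length(t))
  for (w in waves) {
    y <- y + spec$wave_amp[[w]] *
      exp(-0.5 * ((t - spec$wave_offset[[w]]) / spec$wave_width[[w]])^2)
  }
  y
}

#' Generate a synthetic ECG trace with known R-peak ground truth
#'
#' @param spec A [synth_ecg_spec()].
#' @return A list with `signal` (an [ecg_signal()]) and `truth`, a list
#'   whose `r_locs` are exact 0-based R-peak sample indices.
#' @examples
#' out <- synth_ecg(synth_ecg_spec(duration = 10, seed = 1))
#' length(out$truth$r_locs)
#' @export
synth_ecg <- function(spec) {
  stopifnot(inherits(spec, "synth_ecg_spec"))
  with_seed(spec$seed, {
    n <- round(spec$fs * spec$duration)
    tt <- (seq_len(n) - 1) / spec$fs
    period <- 60 / spec$heart_rate

    ## R times on exact sample indices; first beat after the PR interval fits
    r_idx <- integer(0)
    t_r <- max(0.3, -min(spec$wave_offset) + 2 * max(spec$wave_width))
    while (t_r < spec$duration - 0.05) {
      r_idx <- c(r_idx, round(t_r * spec$fs))
      jit <- if (spec$hr_jitter_sd > 0) stats::rnorm(1, 0, spec$hr_jitter_sd) else 0
      t_r <- t_r + max(0.25, period + jit)
    }
    r_idx <- r_idx[r_idx < n]

    x <- numeric(n)
    support <- 0.45  # template support half-width (s)
    for (r in r_idx) {
      lo <- max(0L, r - round(support * spec$fs))
      hi <- min(n - 1L, r + round(support * spec$fs))
      sel <- (lo:hi) + 1L
      x[sel] <- x[sel] + ecg_beat_template(spec, tt[sel] - r / spec$fs)
    }

    clean_power <- mean(x^2)
    sd_w <- spec$white_sd
    if (!is.null(spec$snr_db)) {
      sd_w <- sqrt(clean_power / 10^(spec$snr_db / 10))
    }
    if (spec$powerline_amp > 0) {
      x <- x + spec$powerline_amp * sin(2 * pi * spec$powerline_hz * tt)
    }
    if (spec$baseline_amp > 0) {
      x <- x + spec$baseline_amp * sin(2 * pi * spec$baseline_hz * tt +
                                         stats::runif(1, 0, 2 * pi))
    }
    if (sd_w > 0) x <- x + stats::rnorm(n, 0, sd_w)

    list(signal = ecg_signal(x, spec$fs, "synthetic"),
         truth = list(r_locs = as.integer(r_idx), spec = spec,
                      white_sd = sd_w))
  })
}

#' Specification for a synthetic labeled vector domain
#'
#' Class-conditional Gaussian clusters in `dim` dimensions with controllable
#' class imbalance (exact largest-remainder allocation of `priors`), cluster
#' spread, and an inter-domain mean shift used to build paired
#' source/target domains that share a decision-boundary family.
#'
#' @param n Number of samples.
#' @param dim Feature dimension.
#' @param n_classes Number of classes.
#' @param priors Class prior vector (sums to 1); default uniform.
#' @param delta Inter-domain mean shift: scalar or length-`dim` vector added
#'   to every class mean when `domain = "target"`.
#' @param cov_scale Within-class SD (isotropic).
#' @param class_sep Scale of the randomly drawn class means.
#' @param noise_tail `"gaussian"` (default) or `"logistic"` within-class noise.
#' @param seed RNG seed; class means are derived from it so a source/target
#'   pair generated from the same spec shares means up to `delta`.
#' @return A list of class `synth_domain_spec`.
#' @export
synth_domain_spec <- function(n = 200, dim = 2, n_classes = 2,
                              priors = NULL, delta = 0, cov_scale = 1,
                              class_sep = 3, noise_tail = c("gaussian", "logistic"),
                              seed = NULL) {
  if (is.null(priors)) priors <- rep(1 / n_classes, n_classes)
  if (length(priors) != n_classes) stop_invalid("priors length must equal n_classes")
  if (abs(sum(priors) - 1) > 1e-8) stop_invalid("priors must sum to 1")
  if (any(priors < 0)) stop_invalid("priors must be non-negative")
  if (n < n_classes) stop_invalid("n must be at least n_classes")
  noise_tail <- match.arg(noise_tail)
  structure(as.list(environment()), class = "synth_domain_spec")
}

## exact largest-remainder apportionment of n among priors
allocate_counts <- function(n, priors) {
  raw <- n * priors
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_order <- order(raw - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a labeled vector domain
#'
#' @param spec A [synth_domain_spec()].
#' @param domain `"source"` (means as drawn) or `"target"` (means + `delta`).
#' @return A list with `x` (n x dim matrix), `y` (0-based integer labels),
#'   and `truth` (generating means, counts, spec).
#' @export
synth_domain <- function(spec, domain = c("source", "target")) {
  stopifnot(inherits(spec, "synth_domain_spec"))
  domain <- match.arg(domain)
  means <- with_seed(spec$seed, {
    matrix(stats::rnorm(spec$n_classes * spec$dim, sd = spec$class_sep),
           spec$n_classes, spec$dim)
  })
  shift <- rep(0, spec$dim)
  if (domain == "target") {
    shift <- if (length(spec$delta) == 1) rep(spec$delta, spec$dim) else spec$delta
    if (length(shift) != spec$dim) stop_invalid("delta must be scalar or dim-length")
  }
  draw_seed <- if (is.null(spec$seed)) NULL else {
    spec$seed + if (domain == "target") 1000003L else 0L
  }
  with_seed(draw_seed, {
    counts <- allocate_counts(spec$n, spec$priors)
    y <- rep(seq_len(spec$n_classes) - 1L, counts)
    noise <- if (spec$noise_tail == "gaussian") {
      matrix(stats::rnorm(spec$n * spec$dim, sd = spec$cov_scale), spec$n, spec$dim)
    } else {
      matrix(stats::rlogis(spec$n * spec$dim,
                           scale = spec$cov_scale * sqrt(3) / pi), spec$n, spec$dim)
    }
    x <- means[y + 1L, , drop = FALSE] +
      matrix(shift, spec$n, spec$dim, byrow = TRUE) + noise
    ord <- sample.int(spec$n)
    list(x = x[ord, , drop = FALSE], y = y[ord],
         truth = list(means = means + matrix(shift, spec$n_classes, spec$dim,
                                             byrow = TRUE),
                      counts = counts, spec = spec, domain = domain))
  })
}

#' Bayes-optimal accuracy of a synthetic domain's generating model
#'
#' Monte-Carlo estimate of the accuracy of the Bayes rule (known means,
#' isotropic Gaussian classes, known priors) on fresh draws from the
#' generating distribution; an upper bound for any classifier.
#'
#' @param truth The `truth` element returned by [synth_domain()].
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return Estimated Bayes accuracy in `[0, 1]`.
#' @export
bayes_accuracy <- function(truth, n_mc = 20000, seed = 1) {
  spec <- truth$spec
  with_seed(seed, {
    counts <- allocate_counts(n_mc, spec$priors)
    y <- rep(seq_len(spec$n_classes) - 1L, counts)
    x <- truth$means[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(length(y) * spec$dim, sd = spec$cov_scale),
             length(y), spec$dim)
    ## Bayes rule for isotropic Gaussians: max over classes of
    ## log prior - ||x - mu_c||^2 / (2 sigma^2)
    scores <- sapply(seq_len(spec$n_classes), function(c) {
      log(spec$priors[c] + 1e-300) -
        rowSums(sweep(x, 2, truth$means[c, ])^2) / (2 * spec$cov_scale^2)
    })
    pred <- max.col(scores, ties.method = "first") - 1L
    mean(pred == y)
  })
}

#' Class sizes of the benchmark ECG datasets
#'
#' Published per-class beat counts of the four benchmark ECG corpora
#' (after beat segmentation), used to reproduce their imbalance structure
#' in synthetic profiles.
#'
#' @param dataset One of `"ptb-xl"`, `"mit-bih"`, `"european-st-t"`,
#'   `"long-term-st"`.
#' @return Named integer vector of class sizes (Class 0, 1, ...).
#' @examples
#' imbalance_ratio(benchmark_class_sizes("mit-bih"))
#' @export
benchmark_class_sizes <- function(dataset = c("mit-bih", "ptb-xl",
                                              "european-st-t", "long-term-st")) {
  dataset <- match.arg(dataset)
  sizes <- switch(dataset,
    "ptb-xl" = c(118962, 68410, 65463, 61259, 33108),
    "mit-bih" = c(75052, 8075, 7259, 7130, 7028, 2546, 982, 803, 472, 229,
                  193, 150, 106, 83, 16),
    "european-st-t" = c(780606, 431376, 32760),
    "long-term-st" = c(8832788, 727956))
  names(sizes) <- paste0("class", seq_along(sizes) - 1)
  sizes
}

#' Generate a labeled set of synthetic beats with per-class morphology
#'
#' Each class gets a distinct beat morphology (deterministic per-class
#' scalings of the wave amplitudes and widths) plus white noise, with the
#' exact requested class counts -- e.g., an MIT-BIH-like imbalance profile
#' via `round(benchmark_class_sizes("mit-bih") / 100)`.
#'
#' @param class_sizes Integer vector of per-class counts (all `>= 1`).
#' @param beat_len Samples per beat vector.
#' @param fs Sampling rate implied by the beat template (Hz).
#' @param noise_sd White-noise SD added to every beat.
#' @param seed RNG seed.
#' @return A list with `x` (matrix, one beat per row), `y` (0-based labels),
#'   and `params` (per-class template specs).
#' @export
synth_imbalanced_beats <- function(class_sizes, beat_len = 180, fs = 200,
                                   noise_sd = 0.05, seed = NULL) {
  class_sizes <- as.integer(class_sizes)
  if (any(class_sizes < 1)) stop_invalid("all class sizes must be >= 1")
  n_classes <- length(class_sizes)
  with_seed(seed, {
    t <- seq(-0.45, 0.45, length.out = beat_len)
    params <- lapply(seq_len(n_classes), function(c) {
      ## deterministic distinct morphology per class
      amp_mult <- 1 + 0.35 * sin(c * c(1.3, 2.1, 0.7, 1.9, 2.7))
      width_mult <- 1 + 0.25 * cos(c * c(0.9, 1.7, 1.1, 2.3, 0.5))
      spec <- synth_ecg_spec()
      spec$wave_amp <- spec$wave_amp * amp_mult
      spec$wave_width <- pmax(spec$wave_width * width_mult, 0.005)
      spec
    })
    x <- matrix(0, sum(class_sizes), beat_len)
    y <- integer(sum(class_sizes))
    row <- 1L
    for (c in seq_len(n_classes)) {
      tpl <- ecg_beat_template(params[[c]], t)
      for (i in seq_len(class_sizes[c])) {
        x[row, ] <- tpl + stats::rnorm(beat_len, 0, noise_sd)
        y[row] <- c - 1L
        row <- row + 1L
      }
    }
    list(x = x, y = y, params = params)
  })
}
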