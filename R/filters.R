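#' Rational linear filter in z^-1
#'
#' Represents a causal rational transfer function
#' `H(z) = numerator(z^-1) / denominator(z^-1)` with monic denominator,
#' together with its nominal (design) group delay and gain.
#'
#' @param numerator Numeric coefficients of the numerator polynomial in
#'   ascending powers of `z^-1`.
#' @param denominator Numeric coefficients of the denominator polynomial;
#'   the leading coefficient must equal 1.
#' @param name Descriptive filter label (the detection chain uses
#'   `"highpass"`, `"lowpass"` and `"derivative"`).
#' @param nominal_delay Design group delay in samples (may be `NA`).
#' @param nominal_gain_db Design gain in dB (may be `NA`).
#'
#' @return An object of class `linear_filter`.
#' @export
linear_filter <- function(numerator, denominator = 1, name = "custom",
                          nominal_delay = NA_real_, nominal_gain_db = NA_real_) {
  numerator <- as.numeric(numerator)
  denominator <- as.numeric(denominator)
  if (length(numerator) == 0 || length(denominator) == 0) {
    stop_invalid("coefficient vectors must be non-empty")
  }
  if (denominator[1] != 1) stop_invalid("denominator must be monic")
  if (!is.character(name) || length(name) != 1) {
    stop_invalid("name must be a single string")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 name = name, nominal_delay = nominal_delay,
                 nominal_gain_db = nominal_gain_db),
            class = "linear_filter")
}

#' Build the QRS-detection filter chain
#'
#' Constructs the three linear filters of the Pan-Tompkins-style beat
#' segmentation front end: a high-pass filter that removes baseline wander,
#' a linear-phase low-pass filter `(1 - 2z^-6 + z^-12)/(1 - 2z^-1 + z^-2)`
#' that attenuates powerline and muscle noise (delay 5 samples, DC gain
#' 31 dB), and a linear-phase derivative filter with impulse response
#' `(-1, -2, 2, 1)` that extracts QRS slope information. The coefficients are
#' defined for a nominal 200 Hz design rate; [detect_fiducials()] resamples
#' other rates before applying them.
#'
#' The published high-pass numerator is internally inconsistent with its
#' stated 5 Hz cutoff, so two modes are provided: `"standard"` (default) uses
#' the classical all-pass-minus-low-pass high-pass
#' `(-1 + 32z^-16 - 32z^-17 + z^-32) / (32(1 - z^-1))` with 16 samples delay,
#' while `"literal"` transcribes the printed coefficients verbatim.
#'
#' @param fs Sampling rate in Hz (validated positive; the coefficients are
#'   fixed to the 200 Hz design rate).
#' @param highpass_mode `"standard"` or `"literal"`.
#'
#' @return A named list with elements `highpass`, `lowpass`, `derivative`,
#'   each a [linear_filter()].
#' @examples
#' f <- build_segmentation_filters(200)
#' filter_characteristics(f$lowpass)
#' @export
build_segmentation_filters <- function(fs, highpass_mode = c("standard", "literal")) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs must be positive")
  }
  highpass_mode <- match.arg(highpass_mode)
  if (highpass_mode == "standard") {
    num_hp <- numeric(33)
    num_hp[c(1, 17, 18, 33)] <- c(-1, 32, -32, 1) / 32
    den_hp <- c(1, -1)
  } else {
    num_hp <- numeric(19)
    num_hp[c(1, 7, 8, 13, 17, 19)] <- c(1, -2, -64, 1, 32, 32) / 32
    den_hp <- c(1, -2, 1)
  }
  list(
    highpass = linear_filter(num_hp, den_hp, "highpass",
                             nominal_delay = 16, nominal_gain_db = NA_real_),
    lowpass = linear_filter(c(1, 0, 0, 0, 0, 0, -2, 0, 0, 0, 0, 0, 1),
                            c(1, -2, 1), "lowpass",
                            nominal_delay = 5, nominal_gain_db = 31),
    derivative = linear_filter(c(-1, -2, 2, 1), 1, "derivative",
                               nominal_delay = 2, nominal_gain_db = 14)
  )
}

#' Apply a linear filter to an ECG signal
#'
#' Realizes the rational transfer function as a causal difference equation
#' with zero initial conditions; the output has the same length as the input.
#'
#' @param filter A [linear_filter()].
#' @param signal An [ecg_signal()] (or numeric vector plus `fs`).
#' @param fs Sampling rate, required only when `signal` is a bare vector.
#'
#' @return An [ecg_signal()] with the filtered samples.
#' @export
apply_filter <- function(filter, signal, fs = NULL) {
  stopifnot(inherits(filter, "linear_filter"))
  signal <- as_ecg_signal(signal, fs)
  y <- as.numeric(signal::filter(filt = filter$numerator,
                                 a = filter$denominator,
                                 x = signal$samples))
  if (!all(is.finite(y))) stop_invalid("filter produced non-finite output")
  ecg_signal(y, signal$fs, signal$record_id)
}

#' Square an ECG signal elementwise
#'
#' @param signal An [ecg_signal()] or numeric vector (with `fs`).
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return An [ecg_signal()] with non-negative samples.
#' @export
square_signal <- function(signal, fs = NULL) {
  signal <- as_ecg_signal(signal, fs)
  ecg_signal(signal$samples^2, signal$fs, signal$record_id)
}

#' Moving-window integration
#'
#' Running mean of the `window_n` most recent samples (zero-padded before the
#' start of the signal): `y[n] = (x[n] + x[n-1] + ... + x[n-N+1]) / N`.
#'
#' @param signal An [ecg_signal()] or numeric vector (with `fs`).
#' @param window_n Window length in samples, `1 <= window_n <= length`.
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return An [ecg_signal()] of the same length.
#' @examples
#' moving_window_integration(ecg_signal(c(0, 0, 3, 0, 0), 5), 3)$samples
#' @export
moving_window_integration <- function(signal, window_n, fs = NULL) {
  signal <- as_ecg_signal(signal, fs)
  n <- length(signal$samples)
  window_n <- as.integer(window_n)
  if (length(window_n) != 1 || is.na(window_n) || window_n < 1) {
    stop_invalid("window_n must be a positive integer")
  }
  if (window_n > n) stop_invalid("window_n exceeds signal length")
  cs <- cumsum(signal$samples)
  y <- (cs - c(rep(0, window_n), cs[seq_len(n - window_n)])) / window_n
  ecg_signal(y, signal$fs, signal$record_id)
}

#' Detection thresholds from noise and signal peak levels
#'
#' Computes the two adaptive thresholds used by the QRS detector:
#' `delta1 = PN + 0.25 (PS - PN)` and `delta2 = 0.5 delta1`, where `PN` is
#' the running noise-peak level and `PS` the running signal-peak level of the
#' integrated detection envelope.
#'
#' @param PN Noise peak level (integrated-signal units, `>= 0`).
#' @param PS Signal peak level (`>= PN`).
#' @return An object of class `detector_state` with fields `PN`, `PS`,
#'   `delta1`, `delta2`.
#' @examples
#' compute_thresholds(0, 4)
#' @export
compute_thresholds <- function(PN, PS) {
  if (!is_finite_num(PN) || !is_finite_num(PS)) stop_invalid("levels must be finite")
  if (PN < 0) stop_invalid("PN must be non-negative")
  if (PS < PN) stop_invalid("PS must be >= PN")
  delta1 <- PN + 0.25 * (PS - PN)
  structure(list(PN = PN, PS = PS, delta1 = delta1, delta2 = 0.5 * delta1),
            class = "detector_state")
}

## Polynomial long division of num by den (ascending powers of z^-1).
## Returns the quotient when the remainder vanishes, otherwise NULL.
poly_divide <- function(num, den, tol = 1e-9) {
  nq <- length(num) - length(den) + 1
  if (nq < 1) return(NULL)
  r <- num
  q <- numeric(nq)
  for (i in seq_len(nq)) {
    q[i] <- r[i] / den[1]
    idx <- i:(i + length(den) - 1)
    r[idx] <- r[idx] - q[i] * den
  }
  if (max(abs(r)) > tol * max(1, max(abs(num)))) return(NULL)
  q
}

#' Group delay and DC gain of a linear-phase filter
#'
#' Expands the rational transfer function to its finite impulse response by
#' polynomial long division (the poles must be cancelled by zeros), verifies
#' the coefficient symmetry or antisymmetry of a linear-phase FIR, and
#' returns the group delay `(L - 1) / 2` together with the DC gain
#' `20 log10(|H(1)|)` in dB.
#'
#' @param filter A [linear_filter()].
#' @return A list with `group_delay` (samples), `dc_gain_db` (dB; `-Inf` for
#'   a zero-DC filter such as a derivative), and `impulse_response`.
#' @examples
#' f <- build_segmentation_filters(200)
#' filter_characteristics(f$lowpass) # delay 5, ~31 dB
#' @export
filter_characteristics <- function(filter) {
  stopifnot(inherits(filter, "linear_filter"))
  h <- poly_divide(filter$numerator, filter$denominator)
  if (is.null(h)) {
    stop(errorCondition(
      "filter has no finite impulse response (poles not cancelled by zeros)",
      class = c("distecg_unsupported_filter", "error")))
  }
  ## trim trailing zeros so the symmetry axis is well-defined
  nz <- which(abs(h) > 1e-12)
  if (length(nz) == 0) return(list(group_delay = 0, dc_gain_db = -Inf,
                                   impulse_response = h))
  h <- h[seq_len(max(nz))]
  sym <- max(abs(h - rev(h))) <= 1e-9 * max(abs(h))
  antisym <- max(abs(h + rev(h))) <= 1e-9 * max(abs(h))
  if (!sym && !antisym) {
    stop(errorCondition("impulse response is not linear phase",
                        class = c("distecg_unsupported_filter", "error")))
  }
  dc <- sum(h)
  list(group_delay = (length(h) - 1) / 2,
       dc_gain_db = if (abs(dc) < 1e-12) -Inf else 20 * log10(abs(dc)),
       impulse_response = h)
}
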