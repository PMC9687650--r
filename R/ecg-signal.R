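#' ECG signal container
#'
#' A lightweight container for a single-lead ECG trace: the sample values in
#' millivolts, the sampling rate in Hz, and an opaque record identifier.
#'
#' @param samples Numeric vector of at least two finite sample values (mV).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param record_id Optional character label for the record.
#'
#' @return An object of class `ecg_signal` with fields `samples`, `fs`,
#'   `record_id`.
#' @examples
#' sig <- ecg_signal(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' length(sig$samples)
#' @export
ecg_signal <- function(samples, fs, record_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs must be a positive finite scalar")
  }
  if (length(samples) < 2) stop_invalid("signal must have at least 2 samples")
  if (!all(is.finite(samples))) stop_invalid("all samples must be finite")
  structure(list(samples = samples, fs = fs, record_id = as.character(record_id)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s: %d samples @ %g Hz (%.2f s)\n",
              if (nzchar(x$record_id)) x$record_id else "(unnamed)",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

as_ecg_signal <- function(x, fs = NULL, record_id = "") {
  if (inherits(x, "ecg_signal")) return(x)
  if (is.null(fs)) stop_invalid("fs required when input is a bare vector")
  ecg_signal(x, fs, record_id)
}
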