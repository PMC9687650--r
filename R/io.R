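#' Read an ECG trace from a one-column CSV
#'
#' One sample per row (header optional); the sampling rate comes from the
#' `fs` argument or a sidecar file `<path>.fs` holding a single number.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz (overrides any sidecar).
#' @param record_id Record label (defaults to the file name).
#' @return An [ecg_signal()].
#' @export
read_ecg_csv <- function(path, fs = NULL, record_id = basename(path)) {
  if (is.null(fs)) {
    sidecar <- paste0(path, ".fs")
    if (file.exists(sidecar)) fs <- as.numeric(readLines(sidecar, n = 1))
  }
  if (is.null(fs)) stop_invalid("sampling rate not given and no sidecar found")
  first <- readLines(path, n = 1)
  skip <- if (suppressWarnings(is.na(as.numeric(first)))) 1L else 0L
  x <- utils::read.csv(path, header = FALSE, skip = skip)[[1]]
  ecg_signal(as.numeric(x), fs, record_id)
}

#' Read a labeled feature-vector dataset from a delimited table
#'
#' Numeric table whose last column is an integer class label.
#'
#' @param path File path (comma-, tab- or whitespace-delimited).
#' @param sep Field separator (`""` = any whitespace).
#' @param header Whether the file has a header row.
#' @return A list with `x` (feature matrix) and `y` (0-based integer labels).
#' @export
read_domain_table <- function(path, sep = ",", header = FALSE) {
  d <- utils::read.table(path, sep = sep, header = header)
  if (ncol(d) < 2) stop_invalid("table needs at least one feature + label column")
  list(x = as.matrix(d[, -ncol(d), drop = FALSE]),
       y = as.integer(d[[ncol(d)]]))
}

#' Write fiducials as CSV
#'
#' Columns `beat_index`, `q`, `r`, `s` with 0-based sample indices.
#'
#' @param fiducials A [fiducial_set()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  d <- data.frame(beat_index = seq_along(fiducials$r_locs) - 1L,
                  q = fiducials$q_locs, r = fiducials$r_locs,
                  s = fiducials$s_locs)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read fiducials written by [write_fiducials_csv()]
#'
#' @param path CSV path.
#' @return A [fiducial_set()].
#' @export
read_fiducials_csv <- function(path) {
  d <- utils::read.csv(path)
  fiducial_set(d$q, d$r, d$s)
}

#' Write beat segments as per-beat CSV files
#'
#' @param segments List of [beat_segment()]s.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The written paths, invisibly.
#' @export
write_segments_csv <- function(segments, dir, prefix = "beat") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(segments), function(k) {
    p <- file.path(dir, sprintf("%s_%04d.csv", prefix, k - 1))
    utils::write.csv(data.frame(sample = segments[[k]]$samples), p,
                     row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a WFDB record (formats 16 and 212)
#'
#' Minimal reader for PhysioNet-style records: parses the `.hea` header for
#' the sampling rate, gain and baseline, then decodes the `.dat` signal file
#' (16-bit little-endian or packed 12-bit "212"). Only the first channel is
#' returned, in physical units.
#'
#' @param record Path to the record without extension (e.g. `"dir/100"`).
#' @return An [ecg_signal()].
#' @export
read_wfdb <- function(record) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop_invalid("header not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3) as.numeric(head_f[3]) else 250
  n_samp <- if (length(head_f) >= 4) as.integer(head_f[4]) else NA_integer_
  sig_f <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_file <- file.path(dirname(record), sig_f[1])
  fmt <- sub("x.*$", "", sig_f[2])
  gain <- if (length(sig_f) >= 3) as.numeric(sub("\\(.*$", "", sig_f[3])) else 200
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- 0
  if (length(sig_f) >= 3 && grepl("\\(", sig_f[3])) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", sig_f[3]))
  }
  raw <- readBin(dat_file, "raw", file.info(dat_file)$size)
  if (fmt == "16") {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                 endian = "little", signed = TRUE)
    sig <- v[seq(1, length(v), by = n_sig)]
  } else if (fmt == "212") {
    ## 2 samples packed into 3 bytes
    n_tri <- length(raw) %/% 3
    b <- as.integer(raw[seq_len(3 * n_tri)])
    b1 <- b[seq(1, by = 3, length.out = n_tri)]
    b2 <- b[seq(2, by = 3, length.out = n_tri)]
    b3 <- b[seq(3, by = 3, length.out = n_tri)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0F), 8)
    s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4), 0x0F), 8)
    s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
    s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
    v <- as.vector(rbind(s1, s2))
    sig <- v[seq(1, length(v), by = n_sig)]
  } else {
    stop_invalid("unsupported WFDB format: ", fmt)
  }
  if (!is.na(n_samp) && n_samp > 0) sig <- sig[seq_len(min(length(sig), n_samp))]
  ecg_signal((sig - baseline) / gain, fs, basename(record))
}
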