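#' Fiducial point set
#'
#' Q/R/S landmark locations for a sequence of detected beats. Indices are
#' 0-based sample positions into the signal the detector was given (matching
#' the CSV interchange format written by [write_fiducials_csv()]).
#'
#' @param q_locs,r_locs,s_locs Integer vectors of equal length, strictly
#'   increasing, with `q_locs[k] < r_locs[k] < s_locs[k]` for every beat.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(q_locs = integer(0), r_locs = integer(0),
                         s_locs = integer(0)) {
  q_locs <- as.integer(q_locs); r_locs <- as.integer(r_locs)
  s_locs <- as.integer(s_locs)
  n <- length(r_locs)
  if (length(q_locs) != n || length(s_locs) != n) {
    stop_invalid("q, r, s location vectors must have equal length")
  }
  if (n > 0) {
    if (any(diff(r_locs) <= 0)) stop_invalid("r_locs must be strictly increasing")
    if (any(q_locs >= r_locs) || any(r_locs >= s_locs)) {
      stop_invalid("each beat must satisfy q < r < s")
    }
  }
  structure(list(q_locs = q_locs, r_locs = r_locs, s_locs = s_locs),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d beats\n", length(x$r_locs)))
  invisible(x)
}

#' Detection settings for the QRS detector
#'
#' @param highpass_mode Passed to [build_segmentation_filters()].
#' @param window_ms Moving-integration window (default 150 ms).
#' @param refractory_ms Minimum spacing between accepted R peaks (200 ms).
#' @param qs_search_ms Half-window around R for Q/S localization (100 ms).
#' @param design_fs Design rate of the filter bank (200 Hz); other sampling
#'   rates are polyphase-resampled to this rate and indices mapped back.
#' @param learn_s Length of the initial learning phase used to seed the
#'   running peak levels (default 2 s).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(highpass_mode = "standard", window_ms = 150,
                             refractory_ms = 200, qs_search_ms = 100,
                             design_fs = 200, learn_s = 2) {
  structure(list(highpass_mode = highpass_mode, window_ms = window_ms,
                 refractory_ms = refractory_ms, qs_search_ms = qs_search_ms,
                 design_fs = design_fs, learn_s = learn_s),
            class = "detection_config")
}

## rational approximation of a resampling ratio p/q ~ to/from
resample_ratio <- function(to, from) {
  scale <- 1000
  p <- round(to * scale); q <- round(from * scale)
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(p, q)
  c(p = p / d, q = q / d)
}

#' Detect Q/R/S fiducials in a raw ECG trace
#'
#' Runs the full detection chain -- high-pass, low-pass, derivative,
#' squaring, moving-window integration -- then thresholds integrated-envelope
#' peaks with the adaptive dual thresholds `delta1`/`delta2` of
#' [compute_thresholds()]. The running signal/noise peak levels are updated
#' as `level <- 0.125 peak + 0.875 level`; a search-back pass at `delta2`
#' recovers beats missed during long RR intervals, and a refractory period
#' suppresses double detections (ties broken by larger integrated amplitude,
#' then earlier index). R peaks are localized on the band-passed signal
#' (group-delay compensated, refined on the raw trace); Q and S are the
#' nearest slope sign-changes of the band-passed signal within
#' `qs_search_ms` of each R.
#'
#' @param raw An [ecg_signal()].
#' @param config A [detection_config()].
#' @return A [fiducial_set()] (0-based indices into `raw`). A signal shorter
#'   than one integration window yields an empty set with a warning.
#' @examples
#' sig <- synth_ecg(synth_ecg_spec(duration = 10, seed = 1))
#' det <- detect_fiducials(sig$signal)
#' length(det$r_locs)
#' @export
detect_fiducials <- function(raw, config = detection_config()) {
  stopifnot(inherits(raw, "ecg_signal"))
  dfs <- config$design_fs
  win_n <- max(1L, round(config$window_ms / 1000 * dfs))
  n_design_len <- floor(length(raw$samples) * dfs / raw$fs)
  if (n_design_len < win_n) {
    warning("signal shorter than one integration window; no beats detected")
    return(fiducial_set())
  }

  ## resample to the design rate
  if (abs(raw$fs - dfs) < 1e-9) {
    x <- raw$samples
  } else {
    r <- resample_ratio(dfs, raw$fs)
    x <- as.numeric(signal::resample(raw$samples, r[["p"]], r[["q"]]))
  }
  n <- length(x)

  filters <- build_segmentation_filters(dfs, config$highpass_mode)
  bp <- apply_filter(filters$lowpass, apply_filter(filters$highpass,
                                                   ecg_signal(x, dfs)))
  der <- apply_filter(filters$derivative, bp)
  env <- moving_window_integration(square_signal(der), win_n)$samples
  bp <- bp$samples

  ## band-pass group delay relative to the raw signal
  bp_delay <- filter_characteristics(filters$lowpass)$group_delay +
    filters$highpass$nominal_delay
  refract <- round(config$refractory_ms / 1000 * dfs)

  ## local maxima of the envelope
  d <- diff(env)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(pk) == 0) return(fiducial_set())
  pk_amp <- env[pk]

  ## seed levels from the learning phase
  learn_n <- min(n, max(win_n, round(config$learn_s * dfs)))
  PS <- max(env[seq_len(learn_n)])
  PN <- mean(env[seq_len(learn_n)])
  thr <- compute_thresholds(min(PN, PS), max(PN, PS))

  accepted <- integer(0)    # envelope peak positions of accepted beats
  accepted_amp <- numeric(0)
  noise_pk <- integer(0)    # peaks classified as noise (search-back pool)
  rr_hist <- numeric(0)

  accept <- function(i_pk) {
    amp <- pk_amp[i_pk]
    pos <- pk[i_pk]
    keep <- TRUE
    if (length(accepted) > 0 && pos - accepted[length(accepted)] < refract) {
      ## refractory: keep the larger envelope amplitude, earlier on ties
      if (amp > accepted_amp[length(accepted)]) {
        accepted <<- accepted[-length(accepted)]
        accepted_amp <<- accepted_amp[-length(accepted_amp)]
      } else {
        keep <- FALSE
      }
    }
    if (keep) {
      accepted <<- c(accepted, pos)
      accepted_amp <<- c(accepted_amp, amp)
      PS <<- 0.125 * amp + 0.875 * PS
      if (length(accepted) >= 2) {
        rr_hist <<- utils::tail(c(rr_hist, diff(utils::tail(accepted, 2))), 8)
      }
    }
    keep
  }

  for (i in seq_along(pk)) {
    if (pk_amp[i] >= thr$delta1) {
      accept(i)
    } else {
      PN <- 0.125 * pk_amp[i] + 0.875 * PN
      noise_pk <- c(noise_pk, i)
    }
    thr <- compute_thresholds(min(PN, PS), max(PN, PS))

    ## search-back when the current gap exceeds 166% of the running RR mean
    if (length(rr_hist) >= 1 && length(accepted) > 0) {
      gap_limit <- 1.66 * mean(rr_hist)
      if (pk[i] - accepted[length(accepted)] > gap_limit && length(noise_pk) > 0) {
        in_gap <- noise_pk[pk[noise_pk] > accepted[length(accepted)] &
                             pk[noise_pk] <= pk[i]]
        cand <- in_gap[pk_amp[in_gap] >= thr$delta2]
        if (length(cand) > 0) {
          best <- cand[which.max(pk_amp[cand])]
          if (accept(best)) noise_pk <- setdiff(noise_pk, best)
        }
      }
    }
  }

  if (length(accepted) == 0) return(fiducial_set())

  ## localize R on the band-passed signal behind each envelope peak,
  ## then refine on the raw (design-rate) trace
  qs_n <- round(config$qs_search_ms / 1000 * dfs)
  r_des <- integer(0); q_des <- integer(0); s_des <- integer(0)
  for (pos in accepted) {
    lo <- max(1L, pos - win_n - 5L)
    seg <- abs(bp[lo:pos])
    r_bp <- lo + which.max(seg) - 1L
    r_raw <- r_bp - bp_delay
    lo2 <- max(1L, r_raw - 5L); hi2 <- min(n, r_raw + 5L)
    r_raw <- lo2 + which.max(x[lo2:hi2]) - 1L
    if (r_raw < 2L || r_raw > n - 1L) next

    ## Q/S: nearest slope sign-change of the band-passed signal around R
    r_bp2 <- min(n - 1L, max(2L, r_raw + bp_delay))
    slope <- diff(bp)
    q_i <- NA_integer_; s_i <- NA_integer_
    for (k in seq_len(qs_n)) {
      j <- r_bp2 - k
      if (is.na(q_i) && j >= 2L && sign(slope[j - 1L]) != sign(slope[j])) q_i <- j
      j2 <- r_bp2 + k
      if (is.na(s_i) && j2 <= n - 1L && sign(slope[j2 - 1L]) != sign(slope[j2])) s_i <- j2
      if (!is.na(q_i) && !is.na(s_i)) break
    }
    if (is.na(q_i)) q_i <- r_bp2 - max(1L, round(0.04 * dfs))
    if (is.na(s_i)) s_i <- r_bp2 + max(1L, round(0.04 * dfs))
    q_raw <- max(1L, q_i - bp_delay)
    s_raw <- min(n, s_i - bp_delay)
    if (q_raw >= r_raw) q_raw <- r_raw - 1L
    if (s_raw <= r_raw) s_raw <- r_raw + 1L
    if (q_raw < 1L || s_raw > n) next
    r_des <- c(r_des, r_raw); q_des <- c(q_des, q_raw); s_des <- c(s_des, s_raw)
  }

  if (length(r_des) == 0) return(fiducial_set())
  ord <- order(r_des)
  r_des <- r_des[ord]; q_des <- q_des[ord]; s_des <- s_des[ord]
  keep <- c(TRUE, diff(r_des) > 0)
  r_des <- r_des[keep]; q_des <- q_des[keep]; s_des <- s_des[keep]

  ## map design-rate indices back to the original sampling rate (0-based)
  scale <- raw$fs / dfs
  to0 <- function(i) pmax(0L, pmin(length(raw$samples) - 1L,
                                   as.integer(round((i - 1L) * scale))))
  r0 <- to0(r_des)
  if (abs(scale - 1) > 1e-9) {
    ## refine R on the original trace after index mapping
    half <- max(1L, as.integer(round(0.02 * raw$fs)))
    r0 <- vapply(r0, function(i) {
      lo <- max(0L, i - half); hi <- min(length(raw$samples) - 1L, i + half)
      lo + which.max(raw$samples[(lo + 1L):(hi + 1L)]) - 1L
    }, integer(1))
  }
  q0 <- pmin(to0(q_des), r0 - 1L)
  s0 <- pmax(to0(s_des), r0 + 1L)
  ok <- q0 >= 0L & s0 <= length(raw$samples) - 1L
  sel <- which(ok)
  if (length(sel) > 1) ok[sel[c(FALSE, diff(r0[sel]) <= 0)]] <- FALSE
  fiducial_set(q0[ok], r0[ok], s0[ok])
}

#' Beat segment between two consecutive R waves
#'
#' @param start,end 0-based half-open segment bounds `[start, end)`;
#'   `start` is the left bounding R index and `end` the right one.
#' @param samples The signal slice covered by the segment.
#' @return An object of class `beat_segment` with fields `start`, `end`,
#'   `samples`, `r_left`, `r_right`.
#' @export
beat_segment <- function(start, end, samples) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop_invalid("segment must satisfy end > start")
  if (length(samples) != end - start) stop_invalid("sample slice length mismatch")
  structure(list(start = start, end = end, samples = as.numeric(samples),
                 r_left = start, r_right = end),
            class = "beat_segment")
}

#' Slice a signal into inter-R beat segments
#'
#' A beat is the half-open span `[R_k, R_{k+1})` between consecutive R waves,
#' so `count(R) - 1` segments tile the interval between the first and last R
#' with no gaps or overlaps.
#'
#' @param raw An [ecg_signal()].
#' @param fiducials A [fiducial_set()] (0-based indices into `raw`).
#' @return A list of [beat_segment()] objects (empty if fewer than 2 R peaks).
#' @export
segment_beats <- function(raw, fiducials) {
  stopifnot(inherits(raw, "ecg_signal"), inherits(fiducials, "fiducial_set"))
  r <- fiducials$r_locs
  if (length(r) < 2) return(list())
  lapply(seq_len(length(r) - 1), function(k) {
    beat_segment(r[k], r[k + 1],
                 raw$samples[(r[k] + 1L):r[k + 1L]])
  })
}
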