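test_that("R peaks are recovered exactly on a clean recording", {
  out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 30, heart_rate = 60,
                                  seed = 1))
  det <- detect_fiducials(out$signal)
  expect_s3_class(det, "fiducial_set")
  expect_length(det$r_locs, length(out$truth$r_locs))
  expect_equal(det$r_locs, out$truth$r_locs)
})

test_that("detection works at a non-design sampling rate via resampling", {
  out <- synth_ecg(synth_ecg_spec(fs = 360, duration = 30, heart_rate = 72,
                                  seed = 3))
  det <- detect_fiducials(out$signal)
  expect_length(det$r_locs, length(out$truth$r_locs))
  tol <- round(0.04 * 360)
  err <- vapply(out$truth$r_locs,
                function(r) min(abs(det$r_locs - r)), numeric(1))
  expect_lte(max(err), tol)
})

test_that("fiducial ordering q < r < s holds for every detected beat", {
  out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 20, seed = 4))
  det <- detect_fiducials(out$signal)
  expect_true(all(det$q_locs < det$r_locs))
  expect_true(all(det$r_locs < det$s_locs))
})

test_that("detection is deterministic", {
  out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 15, snr_db = 25,
                                  seed = 6))
  expect_identical(detect_fiducials(out$signal),
                   detect_fiducials(out$signal))
})

test_that("segment count is R count minus one with half-open boundaries", {
  out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 25, seed = 5))
  det <- detect_fiducials(out$signal)
  segs <- segment_beats(out$signal, det)
  expect_length(segs, length(det$r_locs) - 1L)
  ## [R_k, R_{k+1}) tiling: lengths sum to the spanned interval
  lens <- vapply(segs, function(s) length(s$samples), numeric(1))
  expect_equal(sum(lens),
               det$r_locs[length(det$r_locs)] - det$r_locs[1])
  ## consecutive segments abut exactly
  starts <- vapply(segs, `[[`, numeric(1), "start")
  ends <- vapply(segs, `[[`, numeric(1), "end")
  expect_equal(starts, det$r_locs[-length(det$r_locs)])
  expect_equal(ends, det$r_locs[-1])
})

test_that("short or flat signals yield an empty fiducial set", {
  tiny <- ecg_signal(rep(0, 20), fs = 200)  # under one integration window
  expect_warning(det <- detect_fiducials(tiny))
  expect_length(det$r_locs, 0)
  flat <- ecg_signal(rep(0, 2000), fs = 200)
  expect_length(detect_fiducials(flat)$r_locs, 0)
})

test_that("fiducial_set validates ordering", {
  expect_silent(fiducial_set(q_locs = 1L, r_locs = 5L, s_locs = 9L))
  expect_error(fiducial_set(q_locs = 6L, r_locs = 5L, s_locs = 9L),
               class = "distecg_invalid_argument")
})

test_that("the literal high-pass transcription runs end to end", {
  ## the verbatim printed coefficients are kept as a documented alternative;
  ## they are not expected to detect well, only to produce a valid result
  out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 20, seed = 2))
  det <- detect_fiducials(out$signal,
                          detection_config(highpass_mode = "literal"))
  expect_s3_class(det, "fiducial_set")
  if (length(det$r_locs) > 0) {
    expect_true(all(det$q_locs < det$r_locs))
    expect_true(all(det$r_locs < det$s_locs))
  }
})
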