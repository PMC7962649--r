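make_rec <- function(x, fs) {
  tibble::tibble(subject_id = "S001", state = "lying", session = 1L,
                 fs = fs, samples = list(x),
                 truth_r_peaks = list(NULL))
}

band_power <- function(x, fs, f0, half = 0.5) {
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f <- sp$freq * fs
  sum(sp$spec[abs(f - f0) <= half])
}

test_that("the high-pass removes drift and keeps the signal band", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  drift <- sin(2 * pi * 0.2 * t)
  inband <- sin(2 * pi * 10 * t)
  out_d <- ecg_highpass(make_rec(drift, fs))$samples[[1]]
  out_s <- ecg_highpass(make_rec(inband, fs))$samples[[1]]
  expect_lte(sqrt(mean(out_d^2)) / sqrt(mean(drift^2)), 0.10)
  expect_gte(sqrt(mean(out_s^2)) / sqrt(mean(inband^2)), 0.90)
  expect_equal(ecg_highpass(make_rec(numeric(1000), fs))$samples[[1]],
               numeric(1000))
  expect_error(ecg_highpass(make_rec(drift, fs),
                            filter_config(highpass_cutoff = 300)),
               class = "ecgacgan_invalid_argument")
})

test_that("the notch suppresses 60 Hz and spares the passband", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  hum <- sin(2 * pi * 60 * t)
  low <- sin(2 * pi * 5 * t)
  out_h <- ecg_notch(make_rec(hum, fs))$samples[[1]]
  out_l <- ecg_notch(make_rec(low, fs))$samples[[1]]
  atten_db <- 10 * log10(band_power(hum, fs, 60) / band_power(out_h, fs, 60))
  expect_gte(atten_db, 20)
  expect_lte(abs(sqrt(mean(out_l^2)) / sqrt(mean(low^2)) - 1), 0.05)
  expect_equal(ecg_notch(make_rec(numeric(1000), fs))$samples[[1]],
               numeric(1000))
  # idempotent in the stop band: a second pass over an already-notched ECG
  # changes RMS by <= 1%
  bank <- generate_subject_bank(2, seed = 8)
  rec <- synthesize_recording(first_subject(bank), profile_at(70),
                              noise_spec(0, 0.25, 0.2, 0),
                              duration_s = 10, fs = fs, seed = 9)
  once <- ecg_notch(rec)
  twice <- ecg_notch(once)
  r1 <- sqrt(mean(once$samples[[1]]^2))
  r2 <- sqrt(mean(twice$samples[[1]]^2))
  expect_lte(abs(r2 - r1) / r1, 0.01)
})

test_that("QRS detection finds clean beats and rejects silence", {
  bank <- generate_subject_bank(2, seed = 3)
  rec <- synthesize_recording(first_subject(bank), profile_at(60),
                              silent_noise(), duration_s = 10, fs = 500,
                              seed = 5)
  det <- pan_tompkins(rec$samples[[1]], 500)
  truth <- rec$truth_r_peaks[[1]]
  expect_equal(length(det), length(truth))
  expect_true(all(abs(det - truth) <= 0.04 * 500))

  expect_equal(pan_tompkins(numeric(5000), 500), integer(0))
  expect_error(pan_tompkins(numeric(100), 500),
               class = "ecgacgan_invalid_argument")
})

test_that("QRS detection is invariant to global amplitude scaling", {
  bank <- generate_subject_bank(2, seed = 4)
  rec <- synthesize_recording(first_subject(bank), profile_at(70, sd = 3),
                              noise_spec(0.1, 0.25, 0.02, 0.02),
                              duration_s = 20, fs = 500, seed = 6)
  x <- ecg_notch(ecg_highpass(rec))$samples[[1]]
  expect_identical(pan_tompkins(x, 500), pan_tompkins(3 * x, 500))
})

test_that("segmentation extracts normalized fixed-length cycles", {
  bank <- generate_subject_bank(2, seed = 3)
  rec <- synthesize_recording(first_subject(bank), profile_at(60),
                              silent_noise(), duration_s = 12, fs = 500,
                              seed = 5)
  rec$r_peaks <- rec$truth_r_peaks
  cyc <- segment_cycles(rec)
  interior <- sum(rec$truth_r_peaks[[1]] - 0.25 * 500 >= 1 &
                    rec$truth_r_peaks[[1]] + 0.45 * 500 <= 12 * 500)
  expect_equal(nrow(cyc), interior)
  expect_true(all(purrr::map_int(cyc$values, length) == 256))
  expect_true(all(abs(purrr::map_dbl(cyc$values, function(v) max(abs(v))) - 1)
                  < 1e-12))
  # a peak too close to the boundary is dropped and counted
  rec2 <- rec
  rec2$r_peaks <- list(c(10L, rec$truth_r_peaks[[1]]))
  cyc2 <- segment_cycles(rec2)
  expect_equal(nrow(cyc2), interior)
  expect_equal(attr(cyc2, "n_dropped"), attr(cyc, "n_dropped") + 1L)
  # within-subject consistency on noise-free data
  expect_gte(cosine_similarity(cyc$values[[1]], cyc$values[[2]]), 0.99)
})

test_that("sequences are non-overlapping runs of five cycles", {
  cyc <- tibble::tibble(subject_id = "S001", state = "lying", session = 1L,
                        source = "real", cycle_idx = 1:12,
                        values = purrr::map(1:12, function(i) rep(i, 8)))
  seqs <- build_cycle_sequences(cyc)
  expect_equal(nrow(seqs), 2)
  expect_equal(seqs$cycles[[1]][1, ], c(1, 2, 3, 4, 5))
  expect_equal(seqs$cycles[[2]][1, ], c(6, 7, 8, 9, 10))
  expect_equal(nrow(build_cycle_sequences(cyc[1:4, ])), 0)
})

test_that("a minute at rest yields about eleven sequences end to end", {
  bank <- generate_subject_bank(2, seed = 19)
  rec <- synthesize_recording(first_subject(bank), profile_at(60, sd = 1),
                              noise_spec(), duration_s = 60, fs = 500,
                              seed = 7)
  seqs <- rec |>
    ecg_highpass() |>
    ecg_notch() |>
    detect_r_peaks() |>
    segment_cycles() |>
    build_cycle_sequences()
  expect_true(nrow(seqs) >= 10 && nrow(seqs) <= 12)
})
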