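test_that("subject banks are seeded, distinct and respect wave invariants", {
  expect_identical(generate_subject_bank(2, seed = 7),
                   generate_subject_bank(2, seed = 7))
  expect_error(generate_subject_bank(1, seed = 1),
               class = "ecgacgan_invalid_argument")

  bank <- generate_subject_bank(89, seed = 1)
  expect_equal(dplyr::n_distinct(bank$subject_id), 89)
  per <- split(bank, bank$subject_id)
  for (m in per) {
    th <- setNames(m$theta, m$wave)
    amp <- setNames(m$amp, m$wave)
    expect_true(th["P"] < th["Q"] && th["Q"] < 0 && th["R"] == 0 &&
                  0 < th["S"] && th["S"] < th["T"])
    expect_gt(amp["R"], 0)
    expect_true(all(abs(amp["R"]) > abs(amp[c("P", "Q", "S", "T")])))
    expect_true(all(m$width > 0))
  }
  # pairwise distinct morphologies
  sig <- vapply(per, function(m) paste(signif(m$theta, 10), collapse = ","),
                character(1))
  expect_equal(anyDuplicated(sig), 0L)
})

test_that("beat timing follows the state profile", {
  bank <- generate_subject_bank(2, seed = 3)
  m <- first_subject(bank)

  rec <- synthesize_recording(m, profile_at(60), silent_noise(),
                              duration_s = 10, fs = 500, seed = 5)
  pk <- rec$truth_r_peaks[[1]]
  expect_true(abs(length(pk) - 10) <= 1)
  expect_true(all(abs(diff(pk) - 500) <= 1))

  fast <- synthesize_recording(m, profile_at(130, compression = 0.7),
                               silent_noise(), duration_s = 30, fs = 500,
                               seed = 5)
  rr_slow <- mean(diff(rec$truth_r_peaks[[1]])) / 500
  rr_fast <- mean(diff(fast$truth_r_peaks[[1]])) / 500
  expect_lt(abs(rr_fast / rr_slow - 60 / 130), 0.05 * 60 / 130)
})

test_that("powerline noise shows as a 60 Hz spectral peak", {
  bank <- generate_subject_bank(2, seed = 3)
  rec <- synthesize_recording(first_subject(bank), profile_at(60),
                              noise_spec(0, 0.25, 0.1, 0),
                              duration_s = 10, fs = 500, seed = 5)
  sp <- stats::spec.pgram(rec$samples[[1]], plot = FALSE, taper = 0)
  f <- sp$freq * 500
  band <- f > 50 & f < 70
  f_peak <- f[band][which.max(sp$spec[band])]
  expect_lt(abs(f_peak - 60), 1)
})

test_that("ground-truth R peaks sit on local maxima of the clean signal", {
  bank <- generate_subject_bank(3, seed = 9)
  for (sid in unique(bank$subject_id)) {
    rec <- synthesize_recording(bank[bank$subject_id == sid, ],
                                profile_at(75, sd = 4), silent_noise(),
                                duration_s = 20, fs = 500, seed = 17)
    x <- rec$samples[[1]]
    for (p in rec$truth_r_peaks[[1]]) {
      w <- max(1, p - 10):min(length(x), p + 10)
      expect_lte(abs(w[which.max(x[w])] - p), 2)
    }
  }
})

test_that("a study enumerates subjects, states and sessions", {
  study <- generate_study(5, sessions_per_subject = 3, duration_s = 8,
                          fs = 250, seed = 2)
  expect_equal(nrow(study), 5 * 4 * 3)
  expect_equal(anyDuplicated(study[, c("subject_id", "state", "session")]), 0L)
  expect_error(generate_study(3, states = state_profiles()[0, ], seed = 1),
               class = "ecgacgan_invalid_argument")
  expect_error(generate_study(3, sessions_per_subject = 0, seed = 1),
               class = "ecgacgan_invalid_argument")
  expect_identical(generate_study(2, sessions_per_subject = 1, duration_s = 5,
                                  fs = 250, seed = 4),
                   generate_study(2, sessions_per_subject = 1, duration_s = 5,
                                  fs = 250, seed = 4))
})

test_that("measured heart rate orders the acquisition states", {
  study <- generate_study(4, sessions_per_subject = 1, duration_s = 30,
                          fs = 250, seed = 8)
  hr <- study |>
    dplyr::mutate(hr = purrr::map2_dbl(truth_r_peaks, fs, function(p, f) {
      60 / (mean(diff(p)) / f)
    })) |>
    dplyr::group_by(state) |>
    dplyr::summarise(hr = mean(hr)) |>
    tibble::deframe()
  expect_gt(hr[["after_exercise"]], 120)
  expect_gt(hr[["after_exercise"]], hr[["standing"]])
  expect_gte(hr[["standing"]], hr[["before_exercise"]])
  expect_lt(abs(hr[["before_exercise"]] - hr[["lying"]]), 6)
})

test_that("subjects are consistent across sessions and distinct between", {
  study <- generate_study(10, sessions_per_subject = 2, duration_s = 20,
                          fs = 250, seed = 13,
                          states = state_profiles()[1, ])
  cyc <- segment_cycles(study, peaks_col = "truth_r_peaks")
  tmpl <- cyc |>
    dplyr::group_by(subject_id, session) |>
    dplyr::summarise(m = list(Reduce(`+`, values) / length(values)),
                     .groups = "drop")
  # same subject across sessions
  same <- tmpl |>
    tidyr::pivot_wider(names_from = session, values_from = m) |>
    dplyr::mutate(cos = purrr::map2_dbl(`1`, `2`, cosine_similarity))
  expect_true(all(same$cos >= 0.95))
  # different subjects, same state/session: below the same-subject value
  t1 <- tmpl[tmpl$session == 1, ]
  pairs <- t(utils::combn(nrow(t1), 2))
  cross <- apply(pairs, 1, function(ij) {
    cosine_similarity(t1$m[[ij[1]]], t1$m[[ij[2]]])
  })
  expect_gte(mean(cross < min(same$cos)), 0.9)
})
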