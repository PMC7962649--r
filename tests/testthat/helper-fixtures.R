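# Shared fixtures, built once per test session and cached. Heavy objects
# (the trained toy GAN, the end-to-end experiment) are created lazily so the
# first test that needs them pays the cost and the rest reuse it.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# quiet lying-state profile at a given heart rate
profile_at <- function(hr, sd = 0, compression = 1, state = "lying") {
  tibble::tibble(state = state, hr_mean = hr, hr_sd = sd,
                 compression = compression)
}

first_subject <- function(bank) bank[bank$subject_id == bank$subject_id[1], ]

# 3-class cycle bank used by the adversarial-training tests: 60 s x 2
# sessions per subject at 500 Hz, light noise. Training uses the first 200
# cycles per class; the following 40 are held out.
toy_cycles_full <- function() {
  cached("cycles3_full", {
    study <- generate_study(3, sessions_per_subject = 2, duration_s = 60,
                            fs = 500, seed = 11)
    study |>
      ecg_highpass() |>
      ecg_notch() |>
      detect_r_peaks() |>
      segment_cycles()
  })
}

toy_cycles_3class <- function() {
  toy_cycles_full() |>
    dplyr::group_by(subject_id) |>
    dplyr::slice_head(n = 200) |>
    dplyr::ungroup()
}

toy_heldout_cycles <- function(n = 40) {
  toy_cycles_full() |>
    dplyr::group_by(subject_id) |>
    dplyr::slice(201:(200 + n)) |>
    dplyr::ungroup()
}

# the trained toy GAN (3 classes, 200 cycles/class, 300 epochs)
toy_gan_fit <- function() {
  cached("gan3", train_acgan(toy_cycles_3class(),
                             cfg = gan_train_config(epochs = 300, seed = 3)))
}

# small 2-class sequence fixture for fast ensemble unit tests
tiny_sequences <- function() {
  cached("seq2", {
    study <- generate_study(2, sessions_per_subject = 1, duration_s = 40,
                            fs = 250, seed = 33)
    cyc <- segment_cycles(detect_r_peaks(ecg_notch(ecg_highpass(study))),
                          segmentation_config(cycle_len = 64))
    build_cycle_sequences(cyc)
  })
}

# raw periodogram power within +-0.5 Hz of 60 Hz
band_power_60 <- function(x, fs) {
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f <- sp$freq * fs
  sum(sp$spec[abs(f - 60) <= 0.5])
}

# brute-force O(L^2) cross-correlation oracle
xcorr_bruteforce <- function(a, b) {
  L <- length(a)
  r <- vapply(-(L - 1):(L - 1), function(l) {
    t <- seq_len(L)
    tt <- t + l
    ok <- tt >= 1 & tt <= L
    sum(a[tt[ok]] * b[t[ok]])
  }, numeric(1))
  r / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# match detections to truth within a tolerance; returns sensitivity and
# positive predictivity
match_peaks <- function(detected, truth, tol) {
  se <- mean(vapply(truth, function(p) any(abs(detected - p) <= tol),
                    logical(1)))
  ppv <- mean(vapply(detected, function(p) any(abs(truth - p) <= tol),
                     logical(1)))
  c(se = se, ppv = ppv)
}
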