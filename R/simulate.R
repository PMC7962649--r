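#' Default per-wave morphology parameter ranges
#'
#' The simulator draws one morphology per subject: for each of the five
#' characteristic waves (P, Q, R, S, T) a phase angle `theta` (radians
#' relative to the R event at 0), an amplitude `amp` (mV) and a Gaussian
#' `width` (radians). Subjects are sampled uniformly within the ranges
#' returned here, which were chosen to mimic normal adult lead-I morphology:
#' the R deflection dominates, Q and S are small negative deflections flanking
#' it, and the P and T waves sit a quarter cycle before and after the QRS.
#'
#' @return A tibble with one row per wave and columns `wave`, `theta_min`,
#'   `theta_max`, `amp_min`, `amp_max`, `width_min`, `width_max`.
#' @export
#' @examples
#' ecg_wave_ranges()
ecg_wave_ranges <- function() {
  tibble::tribble(
    ~wave, ~theta_min, ~theta_max, ~amp_min, ~amp_max, ~width_min, ~width_max,
    "P",   -1.50,      -1.10,       0.10,     0.25,     0.15,       0.25,
    "Q",   -0.30,      -0.20,      -0.15,    -0.05,     0.06,       0.10,
    "R",    0.00,       0.00,       0.90,     1.60,     0.06,       0.10,
    "S",    0.20,       0.30,      -0.25,    -0.08,     0.06,       0.10,
    "T",    1.00,       1.50,       0.15,     0.40,     0.25,       0.40
  )
}

#' Default acquisition-state profiles
#'
#' Four acquisition states modulate the heart rate and compress the P/T wave
#' timing toward the QRS complex. The post-exercise state keeps the mean heart
#' rate above 120 bpm and uses the strongest timing compression, reflecting
#' the shortened PQ and QT intervals seen at elevated heart rates. Lying and
#' pre-exercise sitting are near-identical resting profiles; standing sits
#' slightly above them.
#'
#' @return A tibble with columns `state`, `hr_mean` (bpm), `hr_sd` (bpm) and
#'   `compression` (factor in (0, 1] applied to the P and T phase angles).
#' @export
#' @examples
#' state_profiles()
state_profiles <- function() {
  tibble::tribble(
    ~state,            ~hr_mean, ~hr_sd, ~compression,
    "lying",            62,       2,      1.00,
    "standing",         72,       3,      0.95,
    "before_exercise",  64,       3,      0.95,
    "after_exercise",  130,       6,      0.70
  )
}

#' Additive noise specification
#'
#' Three independent additive noise sources contaminate simulated recordings:
#' low-frequency baseline drift (respiratory wander, below the 0.5 Hz
#' high-pass corner so preprocessing can remove it), 60 Hz powerline
#' interference, and broadband Gaussian muscle noise.
#'
#' @param baseline_amp Baseline drift amplitude in mV.
#' @param baseline_freq Baseline drift frequency in Hz; must stay below 0.5.
#' @param powerline_amp Powerline interference amplitude in mV (60 Hz).
#' @param broadband_sd Standard deviation of white Gaussian noise in mV.
#' @return A list of class `noise_spec`.
#' @export
#' @examples
#' noise_spec(broadband_sd = 0.05)
noise_spec <- function(baseline_amp = 0.2, baseline_freq = 0.25,
                       powerline_amp = 0.05, broadband_sd = 0.02) {
  if (any(c(baseline_amp, powerline_amp, broadband_sd) < 0)) {
    abort("noise amplitudes must be non-negative", class = "ecgacgan_invalid_argument")
  }
  if (baseline_freq >= 0.5) {
    abort("baseline_freq must be below 0.5 Hz", class = "ecgacgan_invalid_argument")
  }
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp, broadband_sd = broadband_sd),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @details `silent_noise()` is the all-zero specification, for noise-free
#'   fixtures.
#' @export
silent_noise <- function() noise_spec(0, 0.25, 0, 0)

#' Draw a bank of subject morphologies
#'
#' Samples `n_subjects` distinct waveform morphologies, one per simulated
#' subject, uniformly within [ecg_wave_ranges()]. Each morphology satisfies
#' the wave-ordering invariants (P before Q before R before S before T, R
#' dominant, strictly positive widths) by construction of the ranges.
#'
#' @param n_subjects Number of subjects; at least 2 (recognition needs two
#'   classes).
#' @param seed Integer seed; the bank is a pure function of
#'   `(n_subjects, seed)`.
#' @param ranges Parameter ranges as returned by [ecg_wave_ranges()].
#' @return A tibble with five rows per subject and columns `subject_id`,
#'   `wave`, `theta`, `amp`, `width`.
#' @export
#' @examples
#' bank <- generate_subject_bank(3, seed = 1)
#' dplyr::count(bank, subject_id)
generate_subject_bank <- function(n_subjects, seed, ranges = ecg_wave_ranges()) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("n_subjects must be at least 2", class = "ecgacgan_invalid_argument")
  }
  n_subjects <- as.integer(n_subjects)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      tibble::tibble(
        subject_id = sprintf("S%03d", i),
        wave = ranges$wave,
        theta = runif(nrow(ranges), ranges$theta_min, ranges$theta_max),
        amp = runif(nrow(ranges), ranges$amp_min, ranges$amp_max),
        width = runif(nrow(ranges), ranges$width_min, ranges$width_max)
      )
    })
  })
}

# One beat train: R event times and per-beat RR context for a recording.
draw_r_times <- function(hr_mean, hr_sd, duration_s) {
  rr_mean <- 60 / hr_mean
  rr_sd <- hr_sd * 60 / hr_mean^2
  n_max <- ceiling(duration_s / rr_mean * 1.6) + 3
  rr <- pmax(rnorm(n_max, rr_mean, rr_sd), 0.3)
  r_times <- 0.5 * rr[1] + c(0, cumsum(rr[-1]))
  r_times[r_times < duration_s]
}

#' Synthesize one labelled ECG recording
#'
#' Builds a sum-of-Gaussians beat train: every beat contributes five Gaussian
#' deflections (P, Q, R, S, T) placed on a per-beat phase axis, with R-to-R
#' intervals drawn from a truncated normal law set by the state profile, and
#' the P/T phase angles scaled by the state's compression factor. Additive
#' baseline drift, powerline interference and broadband noise follow `noise`.
#' The sample index of every R event is recorded as ground truth.
#'
#' @param morphology Rows of a subject bank for a single subject.
#' @param profile One row of [state_profiles()].
#' @param noise A [noise_spec()].
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for RR intervals and noise.
#' @param session Session index stored in the metadata.
#' @return A one-row tibble with columns `subject_id`, `state`, `session`,
#'   `fs`, `samples` (list of numeric mV) and `truth_r_peaks` (list of
#'   1-based sample indices).
#' @export
#' @examples
#' bank <- generate_subject_bank(2, seed = 1)
#' rec <- synthesize_recording(dplyr::filter(bank, subject_id == "S001"),
#'                             state_profiles()[1, ], noise_spec(),
#'                             duration_s = 10, fs = 500, seed = 2)
#' length(rec$samples[[1]])
synthesize_recording <- function(morphology, profile, noise = noise_spec(),
                                 duration_s = 60, fs = 2000, seed = 1,
                                 session = 1L) {
  if (duration_s <= 0 || fs <= 0) {
    abort("duration_s and fs must be positive", class = "ecgacgan_invalid_argument")
  }
  stopifnot(length(unique(morphology$subject_id)) == 1, nrow(profile) == 1)
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs

  withr::with_seed(seed, {
    r_times <- draw_r_times(profile$hr_mean, profile$hr_sd, duration_s)
    nb <- length(r_times)
    rr_mean <- 60 / profile$hr_mean
    rr <- diff(r_times)
    rr_left <- c(rr_mean, rr)    # RR interval preceding each beat
    rr_right <- c(rr, rr_mean)   # RR interval following each beat

    # assign each sample to the nearest beat, then compute its phase
    bounds <- (r_times[-nb] + r_times[-1]) / 2
    idx <- findInterval(t, bounds) + 1L
    dt <- t - r_times[idx]
    denom <- ifelse(dt < 0, rr_left[idx], rr_right[idx])
    phase <- 2 * pi * dt / denom

    clean <- numeric(n)
    comp <- ifelse(morphology$wave %in% c("P", "T"), profile$compression, 1)
    for (w in seq_len(nrow(morphology))) {
      th <- morphology$theta[w] * comp[w]
      clean <- clean + morphology$amp[w] *
        exp(-((phase - th)^2) / (2 * morphology$width[w]^2))
    }

    x <- clean
    if (noise$baseline_amp > 0) {
      x <- x + noise$baseline_amp *
        sin(2 * pi * noise$baseline_freq * t + runif(1, 0, 2 * pi))
    }
    if (noise$powerline_amp > 0) {
      x <- x + noise$powerline_amp * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))
    }
    if (noise$broadband_sd > 0) {
      x <- x + rnorm(n, 0, noise$broadband_sd)
    }

    peaks <- pmin(pmax(round(r_times * fs) + 1L, 1L), n)
    tibble::tibble(
      subject_id = morphology$subject_id[1],
      state = profile$state,
      session = as.integer(session),
      fs = fs,
      samples = list(as.numeric(x)),
      truth_r_peaks = list(as.integer(peaks))
    )
  })
}

#' Simulate a full acquisition study
#'
#' Emulates a multi-session protocol: every subject is recorded in every
#' acquisition state, `sessions_per_subject` times. The subject morphology is
#' fixed across sessions; the RR-interval and noise random streams differ per
#' recording, so sessions are repeated measurements of the same underlying
#' waveform.
#'
#' @param n_subjects Number of subjects (or a pre-built bank via `bank`).
#' @param states A tibble of state profiles, default [state_profiles()].
#' @param sessions_per_subject Recordings per subject and state (default 3).
#' @param duration_s,fs Recording duration (s) and sampling rate (Hz).
#' @param noise A [noise_spec()].
#' @param seed Master seed; all per-recording streams derive from it.
#' @param bank Optional subject bank; defaults to
#'   `generate_subject_bank(n_subjects, seed)`.
#' @return A tibble of recordings (one row each), as in
#'   [synthesize_recording()].
#' @export
#' @examples
#' study <- generate_study(2, sessions_per_subject = 1, duration_s = 5,
#'                         fs = 250, seed = 1)
#' nrow(study)
generate_study <- function(n_subjects, states = state_profiles(),
                           sessions_per_subject = 3, duration_s = 60,
                           fs = 2000, noise = noise_spec(), seed = 1,
                           bank = NULL) {
  if (nrow(states) == 0) {
    abort("states must be non-empty", class = "ecgacgan_invalid_argument")
  }
  if (sessions_per_subject < 1) {
    abort("sessions_per_subject must be at least 1", class = "ecgacgan_invalid_argument")
  }
  if (is.null(bank)) bank <- generate_subject_bank(n_subjects, seed)
  subjects <- unique(bank$subject_id)

  grid <- tidyr::expand_grid(subject_id = subjects,
                             state = states$state,
                             session = seq_len(sessions_per_subject))
  rec_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, nrow(grid)))

  purrr::pmap_dfr(list(grid$subject_id, grid$state, grid$session, rec_seeds),
    function(sid, st, sess, s) {
      synthesize_recording(bank[bank$subject_id == sid, ],
                           states[states$state == st, ],
                           noise = noise, duration_s = duration_s, fs = fs,
                           seed = s, session = sess)
    })
}
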