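#' Filtering configuration
#'
#' @param highpass_cutoff High-pass corner frequency in Hz for baseline
#'   removal (default 0.5).
#' @param notch_freq Powerline notch centre frequency in Hz (default 60).
#' @param notch_q Notch quality factor; the stop band spans
#'   `notch_freq / notch_q` Hz (default 30).
#' @param filter_order Butterworth order of the high-pass (default 4).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(highpass_cutoff = 0.5, notch_freq = 60,
                          notch_q = 30, filter_order = 4) {
  if (highpass_cutoff <= 0 || notch_freq <= highpass_cutoff ||
      notch_q <= 0 || filter_order < 1) {
    abort("invalid filter configuration", class = "ecgacgan_invalid_argument")
  }
  structure(list(highpass_cutoff = highpass_cutoff, notch_freq = notch_freq,
                 notch_q = notch_q, filter_order = filter_order),
            class = "filter_config")
}

#' Cycle segmentation configuration
#'
#' The cycle window is R-centred and asymmetric: `pre_r_s` seconds before the
#' R peak (covering the P wave) and `post_r_s` seconds after it (covering the
#' T wave). Each window is resampled to exactly `cycle_len` samples and
#' normalized to unit maximum absolute amplitude.
#'
#' @param pre_r_s Seconds before the R peak (default 0.25).
#' @param post_r_s Seconds after the R peak (default 0.45).
#' @param cycle_len Samples per normalized cycle (default 256, at least 32).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(pre_r_s = 0.25, post_r_s = 0.45,
                                cycle_len = 256L) {
  if (pre_r_s <= 0 || post_r_s <= 0 || cycle_len < 32) {
    abort("invalid segmentation configuration", class = "ecgacgan_invalid_argument")
  }
  structure(list(pre_r_s = pre_r_s, post_r_s = post_r_s,
                 cycle_len = as.integer(cycle_len)),
            class = "segmentation_config")
}

apply_to_samples <- function(recordings, f) {
  recordings$samples <- purrr::map2(recordings$samples, recordings$fs, f)
  recordings
}

#' Remove baseline drift with a zero-phase high-pass
#'
#' Applies a forward-backward Butterworth high-pass to every recording, so
#' sub-corner baseline wander (respiration) is removed without shifting the
#' R-peak latency.
#'
#' @param recordings A recordings tibble (see [generate_study()]).
#' @param cfg A [filter_config()].
#' @return The recordings tibble with filtered `samples`; metadata untouched.
#' @export
ecg_highpass <- function(recordings, cfg = filter_config()) {
  apply_to_samples(recordings, function(x, fs) {
    if (fs <= 2 * cfg$highpass_cutoff) {
      abort("high-pass cutoff must be below the Nyquist frequency",
            class = "ecgacgan_invalid_argument")
    }
    bf <- signal::butter(cfg$filter_order, cfg$highpass_cutoff / (fs / 2),
                         type = "high")
    as.numeric(signal::filtfilt(bf, x))
  })
}

#' Suppress powerline interference with a zero-phase notch
#'
#' Applies a forward-backward Butterworth band-stop centred on the powerline
#' frequency (60 Hz by default) to every recording.
#'
#' @inheritParams ecg_highpass
#' @return The recordings tibble with filtered `samples`.
#' @export
ecg_notch <- function(recordings, cfg = filter_config()) {
  apply_to_samples(recordings, function(x, fs) {
    if (fs <= 2 * cfg$notch_freq) {
      abort("notch frequency must be below the Nyquist frequency",
            class = "ecgacgan_invalid_argument")
    }
    bw <- cfg$notch_freq / cfg$notch_q
    edges <- c(cfg$notch_freq - bw / 2, cfg$notch_freq + bw / 2) / (fs / 2)
    bf <- signal::butter(2, edges, type = "stop")
    as.numeric(signal::filtfilt(bf, x))
  })
}

#' Pan-Tompkins QRS detection on a raw signal vector
#'
#' Classical real-time QRS detector: 5-15 Hz band-pass, five-point derivative,
#' squaring, 150 ms moving-window integration, dual adaptive thresholds with
#' search-back, and a 200 ms refractory period. Detections are refined to the
#' local maximum of the band-passed signal within +/-50 ms, so the reported
#' index sits on the R deflection itself. Thresholds adapt multiplicatively,
#' which makes the detector invariant to global amplitude scaling.
#'
#' @param x Numeric signal vector (already high-pass/notch filtered).
#' @param fs Sampling rate in Hz.
#' @return Strictly increasing integer vector of R-peak sample indices.
#' @export
#' @examples
#' rec <- synthesize_recording(
#'   dplyr::filter(generate_subject_bank(2, 1), subject_id == "S001"),
#'   state_profiles()[1, ], noise_spec(0, 0.25, 0, 0),
#'   duration_s = 10, fs = 500, seed = 3)
#' pan_tompkins(rec$samples[[1]], fs = 500)
pan_tompkins <- function(x, fs) {
  if (length(x) < 2 * fs) {
    abort("recording must be at least 2 s long", class = "ecgacgan_invalid_argument")
  }
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, x))
  # five-point derivative, centred (zero phase like the rest of the chain)
  dx <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  dx[is.na(dx)] <- 0
  sq <- as.numeric(dx)^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  if (max(mwi) <= 0) return(integer(0))

  refr <- round(0.2 * fs)
  # candidate peaks: local maxima of the integrated signal
  n <- length(mwi)
  is_peak <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                 mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_peak)
  # keep only peaks that dominate their 200 ms neighbourhood, so integration
  # ripple flanking a QRS cannot claim the refractory period before it
  cand <- cand[vapply(cand, function(p) {
    mwi[p] >= max(mwi[max(1, p - refr):min(n, p + refr)])
  }, logical(1))]
  if (length(cand) == 0) return(integer(0))

  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf
  noise_buf <- integer(0)

  for (p in cand) {
    pk <- mwi[p]
    thr1 <- npki + 0.25 * (spki - npki)
    if (p - last_qrs < refr) next
    if (pk > thr1) {
      qrs <- c(qrs, p)
      if (is.finite(last_qrs)) rr_hist <- utils::tail(c(rr_hist, p - last_qrs), 8)
      last_qrs <- p
      spki <- 0.125 * pk + 0.875 * spki
      noise_buf <- integer(0)
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      noise_buf <- c(noise_buf, p)
      # search-back: no QRS for 1.66 mean RR -> accept best candidate above thr2
      if (length(rr_hist) > 0 && is.finite(last_qrs) &&
          (p - last_qrs) > 1.66 * mean(rr_hist)) {
        thr2 <- 0.5 * thr1
        ok <- noise_buf[mwi[noise_buf] > thr2 & noise_buf - last_qrs >= refr]
        if (length(ok) > 0) {
          sb <- ok[which.max(mwi[ok])]
          qrs <- c(qrs, sb)
          rr_hist <- utils::tail(c(rr_hist, sb - last_qrs), 8)
          last_qrs <- sb
          spki <- 0.25 * mwi[sb] + 0.75 * spki
          noise_buf <- integer(0)
        }
      }
    }
  }
  if (length(qrs) == 0) return(integer(0))

  # refine to the local maximum of the band-passed signal within +/-50 ms
  half <- as.integer(round(0.05 * fs))
  ref <- vapply(qrs, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(ref) >= refr)
  while (!all(keep)) {
    ref <- ref[keep]
    keep <- c(TRUE, diff(ref) >= refr)
  }
  as.integer(ref)
}

#' Detect R peaks in every recording
#'
#' Data-frame verb around [pan_tompkins()]: adds an `r_peaks` list-column to
#' the recordings tibble.
#'
#' @inheritParams ecg_highpass
#' @return The recordings tibble with an `r_peaks` list-column.
#' @export
detect_r_peaks <- function(recordings) {
  recordings$r_peaks <- purrr::map2(recordings$samples, recordings$fs,
                                    pan_tompkins)
  recordings
}

resample_to <- function(x, len) {
  approx(seq_along(x), x, n = len)$y
}

normalize_cycle <- function(v) {
  m <- max(abs(v))
  if (m > 0) v / m else v
}

#' Segment recordings into fixed-length one-cycle units
#'
#' Extracts an R-centred window around every detected peak, resamples it to
#' `cfg$cycle_len` samples and normalizes it to unit maximum absolute
#' amplitude. Peaks whose window overruns the record boundary are dropped
#' (their count is stored in the `n_dropped` attribute).
#'
#' @param recordings A recordings tibble carrying a peak list-column.
#' @param cfg A [segmentation_config()].
#' @param peaks_col Name of the list-column holding peak indices
#'   (`"r_peaks"` from [detect_r_peaks()], or `"truth_r_peaks"` to segment on
#'   simulated ground truth).
#' @param source Source tag stored on every cycle (`"real"` or
#'   `"synthetic"`).
#' @return A cycles tibble: `subject_id`, `state`, `session`, `source`,
#'   `cycle_idx` and a `values` list-column of length-`cycle_len` vectors.
#' @export
segment_cycles <- function(recordings, cfg = segmentation_config(),
                           peaks_col = "r_peaks", source = "real") {
  dropped <- 0L
  out <- purrr::pmap_dfr(
    list(recordings$subject_id, recordings$state, recordings$session,
         recordings$fs, recordings$samples, recordings[[peaks_col]]),
    function(sid, st, sess, fs, x, pk) {
      if (length(pk) == 0) return(NULL)
      pre <- round(cfg$pre_r_s * fs)
      post <- round(cfg$post_r_s * fs)
      ok <- pk - pre >= 1 & pk + post <= length(x)
      dropped <<- dropped + sum(!ok)
      pk <- pk[ok]
      if (length(pk) == 0) return(NULL)
      vals <- purrr::map(pk, function(p) {
        normalize_cycle(resample_to(x[(p - pre):(p + post)], cfg$cycle_len))
      })
      tibble::tibble(subject_id = sid, state = st, session = sess,
                     source = source, cycle_idx = seq_along(pk),
                     values = vals)
    })
  attr(out, "n_dropped") <- dropped
  out
}

#' Assemble non-overlapping five-cycle sequences
#'
#' Groups cycles per (subject, state, session) and cuts each group's ordered
#' cycles into consecutive non-overlapping runs of `n_cycles`. Groups with
#' fewer than `n_cycles` cycles yield no sequence; the trailing remainder of
#' each group is discarded.
#'
#' @param cycles A cycles tibble from [segment_cycles()].
#' @param n_cycles Cycles per sequence (default 5).
#' @return A sequences tibble: `subject_id`, `state`, `session`, `seq_id`,
#'   `scheme` (`"Real1~5"` for all-real sequences) and a `cycles` list-column
#'   of `cycle_len x n_cycles` matrices.
#' @export
build_cycle_sequences <- function(cycles, n_cycles = 5L) {
  cycles |>
    dplyr::group_by(.data$subject_id, .data$state, .data$session) |>
    dplyr::arrange(.data$cycle_idx, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      k <- nrow(g) %/% n_cycles
      if (k == 0) return(tibble::tibble())
      purrr::map_dfr(seq_len(k), function(i) {
        block <- g$values[((i - 1) * n_cycles + 1):(i * n_cycles)]
        tibble::tibble(seq_id = i, scheme = "Real1~5",
                       cycles = list(do.call(cbind, block)))
      })
    }) |>
    dplyr::ungroup()
}
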