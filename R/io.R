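# Plain-text interchange: recordings as two-column CSV (time_s, mv) named
# S{subject}_{state}_{session}.csv with an optional *_rpeaks.txt annotation
# sidecar; cycle banks as wide CSV (metadata columns + v1..v<cycle_len>).

#' Write recordings as two-column CSV files
#'
#' One file per recording, `"<subject>_<state>_<session>.csv"` with columns
#' `time_s` and `mv`; simulated ground-truth R peaks (when present) go to a
#' `*_rpeaks.txt` sidecar of 1-based sample indices.
#'
#' @param recordings A recordings tibble.
#' @param dir Output directory (created if missing).
#' @return Character vector of written CSV paths, invisibly.
#' @export
write_recordings_csv <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    list(recordings$subject_id, recordings$state, recordings$session,
         recordings$fs, recordings$samples,
         recordings$truth_r_peaks %||% vector("list", nrow(recordings))),
    function(sid, st, sess, fs, x, pk) {
      stem <- sprintf("%s_%s_%d", sid, st, sess)
      path <- file.path(dir, paste0(stem, ".csv"))
      readr::write_csv(tibble::tibble(time_s = (seq_along(x) - 1) / fs,
                                      mv = x), path)
      if (!is.null(pk)) {
        writeLines(as.character(pk), file.path(dir, paste0(stem, "_rpeaks.txt")))
      }
      path
    })
  invisible(paths)
}

#' Read recordings written by [write_recordings_csv()]
#'
#' Subject, state and session are recovered from the filename convention;
#' the sampling rate from the time column; R-peak sidecars when present.
#'
#' @param dir Directory of recording CSV files.
#' @return A recordings tibble.
#' @export
read_recordings_csv <- function(dir) {
  files <- sort(list.files(dir, pattern = "^[^_]+_.+_[0-9]+\\.csv$",
                           full.names = TRUE))
  purrr::map_dfr(files, function(f) {
    d <- readr::read_csv(f, show_col_types = FALSE)
    stem <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(stem, "_")[[1]]
    sess <- as.integer(parts[length(parts)])
    sid <- parts[1]
    st <- paste(parts[-c(1, length(parts))], collapse = "_")
    fs <- round(1 / stats::median(diff(d$time_s)))
    side <- file.path(dir, paste0(stem, "_rpeaks.txt"))
    pk <- if (file.exists(side)) as.integer(readLines(side)) else NULL
    tibble::tibble(subject_id = sid, state = st, session = sess, fs = fs,
                   samples = list(d$mv),
                   truth_r_peaks = list(pk))
  })
}

#' Write / read a cycle bank as wide CSV
#'
#' Metadata columns (`subject_id`, `state`, `session`, `source`,
#' `cycle_idx`) followed by one column per sample (`v1` ... `v<cycle_len>`).
#'
#' @param cycles A cycles tibble.
#' @param path CSV path.
#' @return `path` invisibly (writer); a cycles tibble (reader).
#' @export
write_cycles_csv <- function(cycles, path) {
  vals <- do.call(rbind, cycles$values)
  colnames(vals) <- paste0("v", seq_len(ncol(vals)))
  wide <- dplyr::bind_cols(
    cycles[, c("subject_id", "state", "session", "source", "cycle_idx")],
    tibble::as_tibble(vals))
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_cycles_csv
#' @export
read_cycles_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  meta <- c("subject_id", "state", "session", "source", "cycle_idx")
  vals <- as.matrix(wide[, setdiff(names(wide), meta)])
  out <- wide[, meta]
  out$values <- purrr::map(seq_len(nrow(vals)), function(i) unname(vals[i, ]))
  tibble::as_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
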