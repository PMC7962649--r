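#' Plot a stretch of one recording with its R peaks
#'
#' @param recordings A recordings tibble.
#' @param row Which recording to plot (default 1).
#' @param max_s Seconds of signal to show (default 10).
#' @param peaks_col Peak list-column to mark, if present.
#' @return A ggplot object.
#' @export
plot_recording <- function(recordings, row = 1, max_s = 10,
                           peaks_col = "truth_r_peaks") {
  r <- recordings[row, ]
  x <- r$samples[[1]]
  fs <- r$fs
  n <- min(length(x), round(max_s * fs))
  d <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, mv = x[seq_len(n)])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(title = sprintf("%s / %s / session %d", r$subject_id,
                                  r$state, r$session),
                  x = "time (s)", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
  if (peaks_col %in% names(recordings) && !is.null(r[[peaks_col]][[1]])) {
    pk <- r[[peaks_col]][[1]]
    pk <- pk[pk <= n]
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time_s = (pk - 1) / fs, mv = x[pk]),
      colour = "red", size = 1)
  }
  p
}

#' Overlay normalized cycles per subject
#'
#' @param cycles A cycles tibble.
#' @param max_per_subject Cycles drawn per subject (default 15).
#' @return A ggplot object, faceted by subject.
#' @export
plot_cycles <- function(cycles, max_per_subject = 15) {
  d <- cycles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_head(n = max_per_subject) |>
    dplyr::ungroup() |>
    dplyr::mutate(id = dplyr::row_number()) |>
    tidyr::unnest_longer("values", values_to = "mv", indices_to = "sample")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$mv,
                                  group = .data$id,
                                  colour = .data$source)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$subject_id)) +
    ggplot2::labs(x = "sample", y = "normalized amplitude") +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_generation
#' @param object A `similarity_report`.
#' @export
autoplot.similarity_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_class,
                           c("mean_cosine", "mean_xcorr_dist"),
                           names_to = "measure")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject_id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "class", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname train_acgan
#' @param object An `acgan_fit`.
#' @export
autoplot.acgan_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch", names_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "loss") +
    ggplot2::theme_minimal()
}

#' @rdname run_experiment
#' @param object An `ecg_experiment`.
#' @export
autoplot.ecg_experiment <- function(object, ...) {
  d <- dplyr::mutate(object$per_scheme,
                     padded = dplyr::case_when(
                       grepl("Synthetic", .data$scheme) ~ "synthetic",
                       .data$scheme == "Real1~5" ~ "all real",
                       TRUE ~ "repeated"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scheme, y = .data$accuracy,
                                  fill = .data$padded)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(min(d$accuracy) * 0.95, 1)) +
    ggplot2::labs(x = NULL, y = "recognition accuracy", fill = "tail slots") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
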