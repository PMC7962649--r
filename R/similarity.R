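#' Cosine similarity between two equal-length signals
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return The cosine of the angle between `a` and `b`, in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    abort("inputs must have equal length", class = "ecgacgan_invalid_argument")
  }
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0) {
    abort("cosine similarity undefined for a zero vector",
          class = "ecgacgan_invalid_argument")
  }
  # sqrt(sa * sb) rather than sqrt(sa) * sqrt(sb): round-to-nearest then
  # gives exactly +/-1 for (anti)parallel inputs
  sum(a * b) / sqrt(sa * sb)
}

#' Full normalized cross-correlation sequence
#'
#' Returns the cross-correlation of `a` and `b` at every lag from `-(L-1)` to
#' `L-1` (length `2L - 1`), normalized by the product of the vector norms so
#' that the autocorrelation peaks at exactly 1 at zero lag. Lag `l` holds
#' `sum_t a[t + l] * b[t]` (zero-padded), i.e. a positive lag means `a` is
#' shifted left relative to `b`.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Numeric vector of length `2 * length(a) - 1`, lags in increasing
#'   order.
#' @export
#' @examples
#' cross_correlation(c(1, 2, 1), c(0, 1, 0))
cross_correlation <- function(a, b) {
  L <- length(a)
  if (L != length(b)) {
    abort("inputs must have equal length", class = "ecgacgan_invalid_argument")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cross-correlation undefined for a zero vector",
          class = "ecgacgan_invalid_argument")
  }
  # conv(a, rev(b))[m] = sum_j a[j] * b[j - (m - L)]; lag l = m - L
  cc <- convolve(a, b, conj = TRUE, type = "open")
  as.numeric(cc) / (na * nb)
}

#' Cross-correlation Euclidean distance of a synthetic cycle
#'
#' Scores how well a synthetic cycle stands in for the genuine next beat:
#' the cross-correlation waveform of (current, synthetic) is overlaid on the
#' cross-correlation waveform of (current, next real) and their Euclidean
#' distance, scaled by `sqrt(2L - 1)` to be length-independent, is returned.
#' Zero means the synthetic cycle correlates with the current cycle exactly
#' as the real next cycle does; because the correlations are norm-normalized
#' the measure is invariant to amplitude scaling of any input.
#'
#' @param current,next_real,synthetic Numeric vectors of one equal cycle
#'   length.
#' @return Non-negative distance.
#' @export
xcorr_euclidean_distance <- function(current, next_real, synthetic) {
  L <- length(current)
  if (length(next_real) != L || length(synthetic) != L) {
    abort("all three cycles must have equal length",
          class = "ecgacgan_invalid_argument")
  }
  d <- cross_correlation(current, synthetic) - cross_correlation(current, next_real)
  sqrt(sum(d^2) / (2 * L - 1))
}

mean_cycle_by_class <- function(cycles) {
  cycles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mean_cycle = list(Reduce(`+`, .data$values) /
                                         length(.data$values)),
                     .groups = "drop")
}

#' Similarity report for generated cycles
#'
#' Mirrors the two validation measures used for class-conditional ECG
#' generation: per class (subject), the mean cosine similarity between each
#' synthetic cycle and the class's mean real cycle, and the mean
#' cross-correlation Euclidean distance over (current, next real, synthetic)
#' triples formed from consecutive real cycles of one recording and sampled
#' synthetic cycles.
#'
#' @param real_cycles,synthetic_cycles Cycles tibbles ([segment_cycles()]
#'   shape); classes are `subject_id` values and must overlap.
#' @param max_triples Per class, at most this many (current, next, synthetic)
#'   triples are scored (default 200).
#' @param seed Seed for triple subsampling.
#' @return A `similarity_report`: list with `per_class` (tibble of
#'   `subject_id`, `n_synthetic`, `mean_cosine`, `mean_xcorr_dist`) and
#'   `overall` (named list of means).
#' @export
evaluate_generation <- function(real_cycles, synthetic_cycles,
                                max_triples = 200L, seed = 1L) {
  if (nrow(real_cycles) == 0 || nrow(synthetic_cycles) == 0) {
    abort("cycle sets must be non-empty", class = "ecgacgan_invalid_argument")
  }
  classes <- intersect(unique(real_cycles$subject_id),
                       unique(synthetic_cycles$subject_id))
  if (length(classes) == 0) {
    abort("real and synthetic class sets are disjoint",
          class = "ecgacgan_invalid_argument")
  }
  templates <- mean_cycle_by_class(real_cycles)

  per_class <- purrr::map_dfr(classes, function(cl) {
    synth <- synthetic_cycles$values[synthetic_cycles$subject_id == cl]
    tmpl <- templates$mean_cycle[[match(cl, templates$subject_id)]]
    cosines <- purrr::map_dbl(synth, cosine_similarity, b = tmpl)

    # consecutive real cycle pairs within one recording of this class
    rc <- real_cycles[real_cycles$subject_id == cl, ] |>
      dplyr::arrange(.data$state, .data$session, .data$cycle_idx)
    same_run <- rc$state[-nrow(rc)] == rc$state[-1] &
      rc$session[-nrow(rc)] == rc$session[-1] &
      rc$cycle_idx[-1] == rc$cycle_idx[-nrow(rc)] + 1L
    cur_idx <- which(same_run)
    dists <- withr::with_seed(seed, {
      grid <- tidyr::expand_grid(i = cur_idx, j = seq_along(synth))
      if (nrow(grid) > max_triples) {
        grid <- grid[sample.int(nrow(grid), max_triples), ]
      }
      purrr::map2_dbl(grid$i, grid$j, function(i, j) {
        xcorr_euclidean_distance(rc$values[[i]], rc$values[[i + 1]], synth[[j]])
      })
    })
    tibble::tibble(subject_id = cl, n_synthetic = length(synth),
                   mean_cosine = mean(cosines),
                   mean_xcorr_dist = mean(dists))
  })

  structure(list(per_class = per_class,
                 overall = list(mean_cosine = mean(per_class$mean_cosine),
                                mean_xcorr_dist = mean(per_class$mean_xcorr_dist))),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Similarity report over %d classes\n", nrow(x$per_class)))
  cat(sprintf("  overall mean cosine similarity : %.4f\n", x$overall$mean_cosine))
  cat(sprintf("  overall mean x-corr distance   : %.4f\n", x$overall$mean_xcorr_dist))
  invisible(x)
}

#' @rdname evaluate_generation
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @export
tidy.similarity_report <- function(x, ...) {
  dplyr::bind_rows(
    x$per_class,
    tibble::tibble(subject_id = "overall",
                   n_synthetic = sum(x$per_class$n_synthetic),
                   mean_cosine = x$overall$mean_cosine,
                   mean_xcorr_dist = x$overall$mean_xcorr_dist)
  )
}

#' @rdname evaluate_generation
#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$per_class),
                 mean_cosine = x$overall$mean_cosine,
                 mean_xcorr_dist = x$overall$mean_xcorr_dist)
}

#' Write / read a similarity report as CSV
#'
#' One row per class plus an `overall` row, matching [tidy.similarity_report()].
#'
#' @param report A `similarity_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_similarity_csv <- function(report, path) {
  readr::write_csv(tidy(report), path)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
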