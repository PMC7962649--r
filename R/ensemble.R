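#' Configuration for one ensemble member network
#'
#' Each member is a 1D CNN over the flattened five-cycle input: convolution
#' and max-pooling alternate, then a dense (penultimate) stage with dropout
#' feeds a softmax over subjects. In full-scale mode the hyperparameter
#' grid is enforced: epochs in \{500, 750\}, batch size in \{256, 512\},
#' dropout in \[0.50, 0.70\] and learning rate fixed at 0.001 (overridable
#' only by turning `faithful` off).
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param dropout Dropout fraction applied to the penultimate stage.
#' @param lr Adam learning rate.
#' @param channels Conv channels, one per conv/pool block (default two
#'   blocks).
#' @param kernel Odd kernel size.
#' @param pool Pooling factor per block (default 4).
#' @param penult Width of the penultimate dense stage, whose activations are
#'   the member's fused output.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param faithful Enforce the full-scale hyperparameter grid (default TRUE).
#' @return A list of class `member_config`.
#' @export
member_config <- function(epochs = 500L, batch_size = 256L, dropout = 0.5,
                          lr = 0.001, channels = c(6, 12), kernel = 9L,
                          pool = 4L, penult = 48L, seed = 1L,
                          faithful = TRUE) {
  if (faithful) {
    if (!epochs %in% c(500L, 750L)) {
      abort("epochs must be 500 or 750 in full-scale mode",
            class = "ecgacgan_invalid_config")
    }
    if (!batch_size %in% c(256L, 512L)) {
      abort("batch_size must be 256 or 512 in full-scale mode",
            class = "ecgacgan_invalid_config")
    }
    if (dropout < 0.5 || dropout > 0.7) {
      abort("dropout must lie in [0.5, 0.7] in full-scale mode",
            class = "ecgacgan_invalid_config")
    }
    if (lr != 0.001) {
      abort("learning rate is fixed at 0.001 in full-scale mode",
            class = "ecgacgan_invalid_config")
    }
  }
  if (epochs < 1 || batch_size < 1 || dropout < 0 || dropout >= 1 || lr <= 0) {
    abort("invalid member configuration", class = "ecgacgan_invalid_config")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 dropout = dropout, lr = lr, channels = as.integer(channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 penult = as.integer(penult), seed = as.integer(seed),
                 faithful = faithful),
            class = "member_config")
}

#' Build the default six-member hyperparameter grid
#'
#' The four combinations of the epochs and batch-size grid at 50% dropout,
#' plus two members at 70% dropout, each with slight per-member variation in
#' channel widths and kernel size so members detect different features.
#'
#' @param epochs_opts,batch_opts,dropout_opts Grid values; defaults follow
#'   the full-scale grid.
#' @param faithful Passed through to [member_config()].
#' @param seed Base seed; member `i` uses `seed + i`.
#' @return A list of six [member_config()] objects.
#' @export
member_grid <- function(epochs_opts = c(500L, 750L),
                        batch_opts = c(256L, 512L),
                        dropout_opts = c(0.5, 0.7), faithful = TRUE,
                        seed = 1L) {
  base <- tidyr::expand_grid(epochs = epochs_opts, batch = batch_opts)
  extra <- tibble::tibble(epochs = c(epochs_opts[1], epochs_opts[length(epochs_opts)]),
                          batch = c(batch_opts[1], batch_opts[length(batch_opts)]))
  grid <- dplyr::bind_rows(dplyr::mutate(base, dropout = dropout_opts[1]),
                           dplyr::mutate(extra, dropout = dropout_opts[length(dropout_opts)]))
  chans <- list(c(6, 12), c(8, 16), c(6, 12), c(8, 16), c(6, 12), c(8, 16))
  kerns <- c(9L, 9L, 7L, 7L, 9L, 7L)
  purrr::pmap(list(grid$epochs, grid$batch, grid$dropout,
                   seq_len(nrow(grid))),
              function(e, b, d, i) {
                member_config(epochs = e, batch_size = b, dropout = d,
                              channels = chans[[i]], kernel = kerns[i],
                              seed = seed + i, faithful = faithful)
              })
}

sequences_to_matrix <- function(sequences) {
  do.call(cbind, purrr::map(sequences$cycles, as.vector))
}

build_member_net <- function(cfg, input_len, n_classes) {
  layers <- list()
  cin <- 1L
  len <- input_len
  for (ch in cfg$channels) {
    layers <- c(layers, list(layer_conv(cin, ch, cfg$kernel, slope = 0)),
                list(layer_maxpool(cfg$pool)))
    cin <- ch
    len <- len %/% cfg$pool
  }
  layers <- c(layers, list(layer_flatten()),
              list(layer_dense(len * cin, cfg$penult)), list(layer_relu()),
              list(layer_dropout(cfg$dropout)),
              list(layer_dense(cfg$penult, n_classes)))
  layers
}

train_classifier_net <- function(layers, x, y, epochs, batch_size, lr) {
  opt <- adam_init(layers)
  n <- ncol(x)
  bs <- min(batch_size, n)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      fw <- nn_forward(layers, x[, idx, drop = FALSE], training = TRUE)
      ce <- softmax_ce(fw$out, y[idx])
      if (!is.finite(ce$loss)) {
        abort(sprintf("classifier training diverged at epoch %d", ep),
              class = "ecgacgan_training_diverged")
      }
      bw <- nn_backward(layers, fw$caches, ce$grad)
      upd <- adam_step(layers, bw$grads, opt, lr)
      layers <- upd$layers
      opt <- upd$state
    }
  }
  layers
}

# index (within layers) of the penultimate activation: output of the relu
# following the penultimate dense stage
penult_output <- function(layers, x) {
  fw <- nn_forward(layers, x, training = FALSE)
  # recompute up to the dropout layer input: run trunk without the final dense
  fw2 <- nn_forward(layers[seq_len(length(layers) - 2L)], x, training = FALSE)
  list(logits = fw$out, penult = fw2$out)
}

#' Train one ensemble member
#'
#' Trains the member CNN on flattened five-cycle sequences with Adam and
#' softmax cross-entropy, then reports validation accuracy and the
#' penultimate-layer activations of every training input (the member's
#' contribution to the fused registration data).
#'
#' @param train,val Sequence tibbles ([build_cycle_sequences()] shape) with
#'   at least two subjects; `val` must be disjoint from `train`.
#' @param cfg A [member_config()].
#' @param class_levels Optional fixed class ordering (subject ids).
#' @return A list of class `member_result`: `config`, `val_accuracy`,
#'   `fused_train` (inputs x penult matrix), `train_labels`, `class_levels`
#'   and the trained network.
#' @export
train_member <- function(train, val, cfg, class_levels = NULL) {
  if (is.null(class_levels)) class_levels <- sort(unique(train$subject_id))
  if (length(class_levels) < 2) {
    abort("member training needs at least two subjects",
          class = "ecgacgan_invalid_argument")
  }
  x <- sequences_to_matrix(train)
  y <- match(train$subject_id, class_levels)
  xv <- sequences_to_matrix(val)
  yv <- match(val$subject_id, class_levels)

  withr::with_seed(cfg$seed, {
    layers <- build_member_net(cfg, nrow(x), length(class_levels))
    layers <- train_classifier_net(layers, x, y, cfg$epochs, cfg$batch_size,
                                   cfg$lr)
    po_v <- penult_output(layers, xv)
    val_acc <- mean(apply(po_v$logits, 2, which.max) == yv)
    po_t <- penult_output(layers, x)
    structure(list(member_id = NA_integer_, config = cfg,
                   val_accuracy = val_acc,
                   fused_train = t(po_t$penult),
                   train_labels = train$subject_id,
                   class_levels = class_levels, layers = layers),
              class = "member_result")
  })
}

#' Select the top-k members by validation accuracy
#'
#' Ties are broken toward the lower member id, so selection is a pure
#' function of the results.
#'
#' @param results A list of `member_result`s (member ids are assigned by
#'   position if unset).
#' @param k Number of members to keep (default 3).
#' @return The `k` best results, best first.
#' @export
rank_and_select <- function(results, k = 3L) {
  if (length(results) < k) {
    abort("fewer results than k", class = "ecgacgan_invalid_argument")
  }
  for (i in seq_along(results)) {
    if (is.na(results[[i]]$member_id)) results[[i]]$member_id <- i
  }
  acc <- purrr::map_dbl(results, "val_accuracy")
  ids <- purrr::map_int(results, "member_id")
  ord <- order(-acc, ids)
  results[ord[seq_len(k)]]
}

#' Fuse the selected members into one registration set
#'
#' Concatenates, per training input, the penultimate-layer vectors of the
#' selected members; all members must have been trained on the same inputs in
#' the same order.
#'
#' @param selected Exactly three `member_result`s from [rank_and_select()].
#' @return A list with `x` (inputs x 3*penult matrix) and `labels`.
#' @export
build_retraining_set <- function(selected) {
  if (length(selected) != 3) {
    abort("exactly three members are fused", class = "ecgacgan_invalid_argument")
  }
  labs <- purrr::map(selected, "train_labels")
  if (!all(purrr::map_lgl(labs[-1], identical, labs[[1]]))) {
    abort("member outputs are not aligned to the same training inputs",
          class = "ecgacgan_invalid_argument")
  }
  list(x = do.call(cbind, purrr::map(selected, "fused_train")),
       labels = labs[[1]])
}

#' Retrain on fused registration data and recognize comparison sequences
#'
#' A dense softmax classifier (one hidden stage) is retrained on the fused
#' registration features. Each comparison sequence is passed through the
#' three selected members, its penultimate vectors are concatenated, and the
#' retrained classifier assigns a subject. Comparison sequences from subjects
#' unseen at training are counted as errors with a warning.
#'
#' @param fused Output of [build_retraining_set()].
#' @param comparison A sequence tibble of probe sequences.
#' @param selected The three selected `member_result`s (same order as used
#'   for fusing).
#' @param seed Seed for retraining.
#' @param epochs,batch_size,lr,hidden Retraining hyperparameters.
#' @return A list of class `recognition_result`: `accuracy`, `predictions`
#'   tibble and the retrained classifier.
#' @export
retrain_and_recognize <- function(fused, comparison, selected, seed = 1L,
                                  epochs = 60L, batch_size = 32L, lr = 0.001,
                                  hidden = 64L) {
  if (nrow(comparison) == 0) {
    abort("comparison set is empty", class = "ecgacgan_invalid_argument")
  }
  class_levels <- selected[[1]]$class_levels
  unseen <- setdiff(unique(comparison$subject_id), class_levels)
  if (length(unseen) > 0) {
    warn(paste("comparison subjects unseen at training:",
               paste(unseen, collapse = ", ")))
  }
  y <- match(fused$labels, class_levels)

  withr::with_seed(seed, {
    layers <- list(layer_dense(ncol(fused$x), hidden), layer_relu(),
                   layer_dense(hidden, length(class_levels)))
    layers <- train_classifier_net(layers, t(fused$x), y, epochs, batch_size, lr)

    xc <- sequences_to_matrix(comparison)
    feats <- do.call(rbind, purrr::map(selected, function(m) {
      penult_output(m$layers, xc)$penult
    }))
    fw <- nn_forward(layers, feats, training = FALSE)
    pred <- class_levels[apply(fw$out, 2, which.max)]
    correct <- pred == comparison$subject_id
    structure(list(accuracy = mean(correct),
                   predictions = tibble::tibble(
                     subject_id = comparison$subject_id,
                     scheme = comparison$scheme,
                     predicted = pred, correct = correct),
                   classifier = layers, class_levels = class_levels),
              class = "recognition_result")
  })
}

#' Stratified train/validation split of sequences
#'
#' @param sequences A sequence tibble.
#' @param prop Training proportion within each subject (default 0.75).
#' @param seed Seed for the split.
#' @return A list with `train` and `val` tibbles.
#' @export
split_sequences <- function(sequences, prop = 0.75, seed = 1L) {
  withr::with_seed(seed, {
    idx <- sequences |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_sample(prop = prop) |>
      dplyr::pull(.data$.row)
  })
  list(train = sequences[sort(idx), ], val = sequences[-sort(idx), ])
}

#' Train the parallel ensemble and fuse its top members
#'
#' Trains every configured member on a stratified split of the registration
#' sequences, ranks members by validation accuracy, fuses the top three into
#' a retraining set and retrains the final classifier.
#'
#' @param sequences Registration sequence tibble.
#' @param configs List of [member_config()]s (default [member_grid()]).
#' @param seed Master seed for the split and retraining.
#' @param top_k Members fused (fixed at 3 by the method; exposed for
#'   completeness).
#' @return A list of class `ensemble_fit`: members, selected ids, fused set
#'   and metadata needed to recognize probes via [predict_ensemble()].
#' @export
train_ensemble <- function(sequences, configs = member_grid(), seed = 1L,
                           top_k = 3L) {
  sp <- split_sequences(sequences, seed = seed)
  class_levels <- sort(unique(sequences$subject_id))
  results <- purrr::imap(configs, function(cfg, i) {
    r <- train_member(sp$train, sp$val, cfg, class_levels = class_levels)
    r$member_id <- i
    r
  })
  selected <- rank_and_select(results, k = top_k)
  fused <- build_retraining_set(selected)
  structure(list(members = results, selected = selected,
                 selected_ids = purrr::map_int(selected, "member_id"),
                 fused = fused, class_levels = class_levels, seed = seed),
            class = "ensemble_fit")
}

#' Recognize probe sequences with a trained ensemble
#'
#' @param fit An `ensemble_fit`.
#' @param comparison Probe sequence tibble.
#' @param seed Seed for the retraining stage.
#' @return A `recognition_result` (see [retrain_and_recognize()]).
#' @export
predict_ensemble <- function(fit, comparison, seed = fit$seed) {
  retrain_and_recognize(fit$fused, comparison, fit$selected, seed = seed)
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("Ensemble of %d members, top-%d fused (members %s)\n",
              length(x$members), length(x$selected),
              paste(x$selected_ids, collapse = ", ")))
  print(tidy(x))
  invisible(x)
}

#' @rdname train_ensemble
#' @param x An `ensemble_fit`.
#' @param ... Unused.
#' @export
tidy.ensemble_fit <- function(x, ...) {
  purrr::map_dfr(x$members, function(m) {
    tibble::tibble(member_id = m$member_id, epochs = m$config$epochs,
                   batch_size = m$config$batch_size,
                   dropout = m$config$dropout,
                   val_accuracy = m$val_accuracy,
                   selected = m$member_id %in% x$selected_ids)
  })
}

#' @rdname train_ensemble
#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble::tibble(n_members = length(x$members),
                 best_val_accuracy = max(purrr::map_dbl(x$members, "val_accuracy")),
                 n_subjects = length(x$class_levels))
}
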