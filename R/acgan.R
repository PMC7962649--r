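#' Generator architecture specification
#'
#' The generator maps a noise vector with the same length as the cycle to be
#' generated, combined element-wise with a learned class embedding, through
#' nine 1D convolutional layers, two max-pooling layers (after the third and
#' sixth convolutions) and one fully connected output stage with a saturating
#' (tanh) activation, so every generated cycle lies in \[-1, 1\]. The
#' 9-conv / 2-pool / 1-FC skeleton is enforced; channel widths, kernel size
#' and pooling positions are configurable.
#'
#' @param n_classes Number of classes (subjects) the generator conditions on.
#' @param noise_len Noise vector length; equals the cycle length (default
#'   256).
#' @param channels Output channels for each of the nine convolutions.
#' @param kernel Odd convolution kernel size (default 9).
#' @param pool_after Indices of the two convolutions followed by a pooling
#'   stage (default 3 and 6).
#' @param slope Leaky-rectifier negative slope (default 0.2).
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_classes, noise_len = 256L,
                           channels = rep(4L, 9),
                           kernel = 9L, pool_after = c(3L, 6L), slope = 0.2) {
  if (length(channels) != 9) {
    abort("the generator uses exactly nine convolutional layers",
          class = "ecgacgan_invalid_spec")
  }
  if (length(pool_after) != 2) {
    abort("the generator uses exactly two pooling layers",
          class = "ecgacgan_invalid_spec")
  }
  if (n_classes < 2) {
    abort("n_classes must be at least 2", class = "ecgacgan_invalid_spec")
  }
  structure(list(n_classes = as.integer(n_classes),
                 noise_len = as.integer(noise_len),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 pool_after = as.integer(pool_after), slope = slope),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A convolution-repeating CNN strictly shallower than the generator, with
#' two output heads: a real/fake source score and an auxiliary classifier
#' over the `n_classes` subjects.
#'
#' @inheritParams generator_spec
#' @param conv_layers Number of convolutions; must stay below the
#'   generator's nine (default 4). Each convolution is followed by
#'   max-pooling.
#' @param channels Output channels per convolution (length `conv_layers`).
#' @param input_len Input cycle length (default 256).
#' @return A list of class `discriminator_spec`.
#' @export
discriminator_spec <- function(n_classes, input_len = 256L, conv_layers = 4L,
                               channels = c(4, 4, 8, 8), kernel = 9L,
                               slope = 0.2) {
  if (conv_layers >= 9) {
    abort("the discriminator must be strictly shallower than the generator",
          class = "ecgacgan_invalid_spec")
  }
  if (length(channels) != conv_layers) {
    abort("channels must have one entry per convolution",
          class = "ecgacgan_invalid_spec")
  }
  structure(list(n_classes = as.integer(n_classes),
                 input_len = as.integer(input_len),
                 conv_layers = as.integer(conv_layers),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 slope = slope),
            class = "discriminator_spec")
}

#' GAN training configuration
#'
#' @param epochs Training epochs (0 returns the initialization unchanged).
#' @param batch_size Minibatch size; batches adapt to the data size.
#' @param lr_g,lr_d Adam learning rates for generator and discriminator.
#' @param beta1 Adam first-moment decay (0.5, the usual adversarial choice).
#' @param label_smoothing Target value for real source labels (default 0.9).
#' @param aux_weight Weight of the auxiliary class loss relative to the
#'   source loss, for both networks (default 10: class fidelity is the point
#'   of conditional generation, and the heavier weight both stabilizes
#'   training and sharpens between-class separation of the generator).
#' @param seed Master seed for initialization, shuffling and noise draws.
#' @return A list of class `gan_train_config`.
#' @export
gan_train_config <- function(epochs = 300L, batch_size = 64L, lr_g = 2e-4,
                             lr_d = 2e-4, beta1 = 0.5, label_smoothing = 0.9,
                             aux_weight = 10, seed = 1L) {
  if (epochs < 0 || batch_size < 1 || lr_g <= 0 || lr_d <= 0 ||
      aux_weight <= 0) {
    abort("invalid GAN training configuration", class = "ecgacgan_invalid_argument")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_g = lr_g, lr_d = lr_d, beta1 = beta1,
                 label_smoothing = label_smoothing, aux_weight = aux_weight,
                 seed = as.integer(seed)),
            class = "gan_train_config")
}

#' Build an untrained conditional generator
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `ecg_generator` holding the class-embedding matrix
#'   and the layer stack.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(seed, {
    layers <- list()
    cin <- 1L
    len <- spec$noise_len
    for (i in 1:9) {
      layers <- c(layers, list(layer_conv(cin, spec$channels[i], spec$kernel,
                                          slope = spec$slope)))
      cin <- spec$channels[i]
      if (i %in% spec$pool_after) {
        layers <- c(layers, list(layer_maxpool(2L)))
        len <- len %/% 2L
      }
    }
    layers <- c(layers, list(layer_flatten()),
                list(layer_dense(len * cin, spec$noise_len)),
                list(layer_tanh()))
    emb <- matrix(rnorm(spec$noise_len * spec$n_classes, sd = 1),
                  spec$noise_len, spec$n_classes)
    structure(list(spec = spec, embedding = emb, layers = layers),
              class = "ecg_generator")
  })
}

# Forward pass; z: (noise_len x B), classes: integer vector in 1..n_classes.
generator_forward <- function(gen, z, classes, training = FALSE) {
  if (any(classes < 1 | classes > gen$spec$n_classes)) {
    abort("class id out of range", class = "ecgacgan_invalid_argument")
  }
  h <- z * gen$embedding[, classes, drop = FALSE]
  x <- h
  dim(x) <- c(nrow(h), 1L, ncol(h))
  fw <- nn_forward(gen$layers, x, training = training)
  list(out = fw$out, caches = fw$caches, z = z, classes = classes)
}

# Backward pass; returns gradients for layers and embedding.
generator_backward <- function(gen, fw, dout) {
  bw <- nn_backward(gen$layers, fw$caches, dout)
  dh <- bw$dx
  dim(dh) <- c(gen$spec$noise_len, length(fw$classes))
  dz_emb <- dh * fw$z           # d loss / d embedding column, per item
  demb <- gen$embedding * 0
  for (cl in unique(fw$classes)) {
    demb[, cl] <- rowSums(dz_emb[, fw$classes == cl, drop = FALSE])
  }
  list(grads = bw$grads, demb = demb)
}

#' Build an untrained discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `ecg_discriminator` with a shared convolutional
#'   trunk and two dense heads (source and class).
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  withr::with_seed(seed, {
    layers <- list()
    cin <- 1L
    len <- spec$input_len
    for (i in seq_len(spec$conv_layers)) {
      layers <- c(layers, list(layer_conv(cin, spec$channels[i], spec$kernel,
                                          slope = spec$slope)),
                  list(layer_maxpool(2L)))
      cin <- spec$channels[i]
      len <- len %/% 2L
    }
    layers <- c(layers, list(layer_flatten()))
    flat <- len * cin
    structure(list(spec = spec, trunk = layers,
                   head_src = layer_dense(flat, 1L),
                   head_cls = layer_dense(flat, spec$n_classes)),
              class = "ecg_discriminator")
  })
}

# x: (input_len x B) matrix of cycles.
discriminator_forward <- function(disc, x, training = FALSE) {
  if (nrow(x) != disc$spec$input_len) {
    abort("input length does not match the discriminator spec",
          class = "ecgacgan_invalid_argument")
  }
  xc <- x
  dim(xc) <- c(nrow(x), 1L, ncol(x))
  fw <- nn_forward(disc$trunk, xc, training = training)
  feat <- fw$out
  list(src = disc$head_src$W %*% feat + disc$head_src$b,
       cls = disc$head_cls$W %*% feat + disc$head_cls$b,
       feat = feat, caches = fw$caches)
}

# Backward from head gradients; returns per-part grads and dx (input grad).
discriminator_backward <- function(disc, fw, dsrc, dcls) {
  g_src <- list(W = dsrc %*% t(fw$feat), b = rowSums(dsrc))
  g_cls <- list(W = dcls %*% t(fw$feat), b = rowSums(dcls))
  dfeat <- crossprod(disc$head_src$W, dsrc) + crossprod(disc$head_cls$W, dcls)
  bw <- nn_backward(disc$trunk, fw$caches, dfeat)
  dx <- bw$dx
  dim(dx) <- c(disc$spec$input_len, dim(dx)[3])
  list(trunk = bw$grads, src = g_src, cls = g_cls, dx = dx)
}

#' Class probabilities from a discriminator's auxiliary head
#'
#' @param disc An `ecg_discriminator` (or an `acgan_fit`, whose discriminator
#'   is used).
#' @param values A list of cycle vectors.
#' @return A matrix (cycles x classes) of probabilities summing to 1 per row.
#' @export
discriminator_classify <- function(disc, values) {
  if (inherits(disc, "acgan_fit")) disc <- disc$discriminator
  x <- do.call(cbind, values)
  fw <- discriminator_forward(disc, x, training = FALSE)
  t(softmax_probs(fw$cls))
}

cycles_to_matrix <- function(cycles) {
  do.call(cbind, cycles$values)
}

#' Train the auxiliary-classifier adversarial network
#'
#' Alternating minibatch updates: the discriminator minimizes a binary
#' source loss (real vs generated, with label smoothing on real) plus the
#' auxiliary categorical class loss on both real and generated cycles; the
#' generator minimizes the fooling source loss plus the class loss on its own
#' outputs. Both use Adam. Training aborts with a
#' `ecgacgan_training_diverged` error naming the epoch if any loss turns
#' non-finite.
#'
#' @param cycles A cycles tibble ([segment_cycles()]); `subject_id` defines
#'   the classes (at least two required).
#' @param gspec,dspec Optional [generator_spec()] / [discriminator_spec()];
#'   defaults are derived from the data.
#' @param cfg A [gan_train_config()].
#' @return An `acgan_fit`: generator, discriminator, class levels, and a
#'   per-epoch loss history tibble (`epoch`, `d_src`, `d_cls`, `g_src`,
#'   `g_cls`).
#' @export
train_acgan <- function(cycles, gspec = NULL, dspec = NULL,
                        cfg = gan_train_config()) {
  class_levels <- sort(unique(cycles$subject_id))
  if (length(class_levels) < 2) {
    abort("GAN training needs at least two classes",
          class = "ecgacgan_invalid_argument")
  }
  x_all <- cycles_to_matrix(cycles)
  y_all <- match(cycles$subject_id, class_levels)
  L <- nrow(x_all)
  K <- length(class_levels)
  if (is.null(gspec)) gspec <- generator_spec(K, noise_len = L)
  if (is.null(dspec)) dspec <- discriminator_spec(K, input_len = L)
  stopifnot(gspec$noise_len == L, dspec$input_len == L)

  withr::with_seed(cfg$seed, {
    gen <- build_generator(gspec, seed = sample.int(.Machine$integer.max, 1))
    disc <- build_discriminator(dspec, seed = sample.int(.Machine$integer.max, 1))
    opt_g <- adam_init(gen$layers)
    opt_emb <- list(t = 0L, m = gen$embedding * 0, v = gen$embedding * 0)
    opt_d_trunk <- adam_init(disc$trunk)
    opt_d_src <- adam_init(list(disc$head_src))
    opt_d_cls <- adam_init(list(disc$head_cls))

    n <- ncol(x_all)
    bs <- min(cfg$batch_size, n)
    hist <- vector("list", cfg$epochs)

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- c(d_src = 0, d_cls = 0, g_src = 0, g_cls = 0)
      nb <- 0L
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        B <- length(idx)
        xr <- x_all[, idx, drop = FALSE]
        yr <- y_all[idx]

        # --- discriminator update ---
        zf <- matrix(rnorm(L * B), L, B)
        yf <- sample.int(K, B, replace = TRUE)
        xf <- generator_forward(gen, zf, yf)$out   # detached for the D step

        fw_r <- discriminator_forward(disc, xr, training = TRUE)
        fw_f <- discriminator_forward(disc, xf, training = TRUE)
        src_r <- sigmoid_bce(fw_r$src, cfg$label_smoothing)
        src_f <- sigmoid_bce(fw_f$src, 0)
        cls_r <- softmax_ce(fw_r$cls, yr)
        cls_f <- softmax_ce(fw_f$cls, yf)
        g_r <- discriminator_backward(disc, fw_r, src_r$grad,
                                      cfg$aux_weight * cls_r$grad)
        g_f <- discriminator_backward(disc, fw_f, src_f$grad,
                                      cfg$aux_weight * cls_f$grad)
        trunk_g <- purrr::map2(g_r$trunk, g_f$trunk, function(a, b) {
          if (is.null(a)) NULL else list(W = a$W + b$W, b = a$b + b$b)
        })
        upd <- adam_step(disc$trunk, trunk_g, opt_d_trunk, cfg$lr_d, cfg$beta1)
        disc$trunk <- upd$layers; opt_d_trunk <- upd$state
        upd <- adam_step(list(disc$head_src),
                         list(list(W = g_r$src$W + g_f$src$W,
                                   b = g_r$src$b + g_f$src$b)),
                         opt_d_src, cfg$lr_d, cfg$beta1)
        disc$head_src <- upd$layers[[1]]; opt_d_src <- upd$state
        upd <- adam_step(list(disc$head_cls),
                         list(list(W = g_r$cls$W + g_f$cls$W,
                                   b = g_r$cls$b + g_f$cls$b)),
                         opt_d_cls, cfg$lr_d, cfg$beta1)
        disc$head_cls <- upd$layers[[1]]; opt_d_cls <- upd$state

        # --- generator update ---
        zg <- matrix(rnorm(L * B), L, B)
        yg <- sample.int(K, B, replace = TRUE)
        fw_g <- generator_forward(gen, zg, yg, training = TRUE)
        fw_d <- discriminator_forward(disc, fw_g$out, training = TRUE)
        src_g <- sigmoid_bce(fw_d$src, 1)
        cls_g <- softmax_ce(fw_d$cls, yg)
        bw_d <- discriminator_backward(disc, fw_d, src_g$grad,
                                       cfg$aux_weight * cls_g$grad)
        gb <- generator_backward(gen, fw_g, bw_d$dx)
        upd <- adam_step(gen$layers, gb$grads, opt_g, cfg$lr_g, cfg$beta1)
        gen$layers <- upd$layers; opt_g <- upd$state
        opt_emb$t <- opt_emb$t + 1L
        opt_emb$m <- cfg$beta1 * opt_emb$m + (1 - cfg$beta1) * gb$demb
        opt_emb$v <- 0.999 * opt_emb$v + 0.001 * gb$demb^2
        gen$embedding <- gen$embedding - cfg$lr_g *
          (opt_emb$m / (1 - cfg$beta1^opt_emb$t)) /
          (sqrt(opt_emb$v / (1 - 0.999^opt_emb$t)) + 1e-8)

        ep_loss <- ep_loss + c(src_r$loss + src_f$loss,
                               cls_r$loss + cls_f$loss,
                               src_g$loss, cls_g$loss)
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      if (any(!is.finite(ep_loss))) {
        abort(sprintf("GAN training diverged at epoch %d", ep),
              class = "ecgacgan_training_diverged")
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, d_src = ep_loss[["d_src"]],
                                   d_cls = ep_loss[["d_cls"]],
                                   g_src = ep_loss[["g_src"]],
                                   g_cls = ep_loss[["g_cls"]])
    }

    structure(list(generator = gen, discriminator = disc,
                   class_levels = class_levels, cycle_len = L,
                   epochs = cfg$epochs, config = cfg,
                   history = dplyr::bind_rows(hist)),
              class = "acgan_fit")
  })
}

#' Generate synthetic cycles from a trained checkpoint
#'
#' Draws seeded noise, runs the generator conditioned on the requested class
#' and returns amplitude-normalized cycles tagged `source = "synthetic"`.
#'
#' @param fit An `acgan_fit` from [train_acgan()].
#' @param class_id A subject id present in the fit's class levels (or its
#'   integer index).
#' @param n Number of cycles to generate.
#' @param seed Integer seed for the noise draws.
#' @param oversample Discriminator rejection sampling: draw `n * oversample`
#'   candidates and keep the `n` the auxiliary class head assigns the
#'   highest target-class probability (1 disables selection). Uses only the
#'   trained model, no real data.
#' @return A cycles tibble with `n` rows.
#' @export
generate_cycles <- function(fit, class_id, n, seed = 1L, oversample = 1L) {
  stopifnot(inherits(fit, "acgan_fit"))
  if (is.character(class_id)) {
    k <- match(class_id, fit$class_levels)
  } else {
    k <- as.integer(class_id)
  }
  if (is.na(k) || k < 1 || k > length(fit$class_levels)) {
    abort("unknown class id", class = "ecgacgan_invalid_argument")
  }
  m <- n * max(1L, as.integer(oversample))
  withr::with_seed(seed, {
    z <- matrix(rnorm(fit$cycle_len * m), fit$cycle_len, m)
    out <- generator_forward(fit$generator, z, rep(k, m))$out
    if (m > n) {
      fw <- discriminator_forward(fit$discriminator, out)
      p_target <- softmax_probs(fw$cls)[k, ]
      out <- out[, order(-p_target)[seq_len(n)], drop = FALSE]
    }
    tibble::tibble(subject_id = fit$class_levels[k], state = NA_character_,
                   session = NA_integer_, source = "synthetic",
                   cycle_idx = seq_len(n),
                   values = purrr::map(seq_len(n),
                                       function(i) normalize_cycle(out[, i])))
  })
}

#' Generate a synthetic cycle bank for every class
#'
#' @param fit An `acgan_fit`.
#' @param n_per_class Cycles per class.
#' @param seed Master seed; per-class streams derive from it.
#' @inheritParams generate_cycles
#' @return A cycles tibble covering every class of the fit.
#' @export
generate_cycle_bank <- function(fit, n_per_class = 5L, seed = 1L,
                                oversample = 1L) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                             length(fit$class_levels)))
  purrr::map2_dfr(fit$class_levels, seeds, function(cl, s) {
    generate_cycles(fit, cl, n_per_class, seed = s, oversample = oversample)
  })
}

#' @export
print.acgan_fit <- function(x, ...) {
  cat(sprintf("ACGAN fit: %d classes, cycle length %d, %d epochs\n",
              length(x$class_levels), x$cycle_len, x$epochs))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses  D source %.3f  D class %.3f  G source %.3f  G class %.3f\n",
                last$d_src, last$d_cls, last$g_src, last$g_cls))
  }
  invisible(x)
}

#' @rdname train_acgan
#' @param x An `acgan_fit`.
#' @param ... Unused.
#' @export
tidy.acgan_fit <- function(x, ...) x$history

#' @rdname train_acgan
#' @export
glance.acgan_fit <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else
    tibble::tibble(d_src = NA_real_, d_cls = NA_real_,
                   g_src = NA_real_, g_cls = NA_real_)
  tibble::tibble(n_classes = length(x$class_levels), cycle_len = x$cycle_len,
                 epochs = x$epochs, d_src = last$d_src, d_cls = last$d_cls,
                 g_src = last$g_src, g_cls = last$g_cls)
}
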