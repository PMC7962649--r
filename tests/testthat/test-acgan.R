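test_that("architecture specs enforce the fixed skeleton", {
  expect_error(generator_spec(3, channels = rep(8, 8)),
               class = "ecgacgan_invalid_spec")
  expect_error(generator_spec(3, pool_after = 3L),
               class = "ecgacgan_invalid_spec")
  expect_error(discriminator_spec(3, conv_layers = 9,
                                  channels = rep(8, 9)),
               class = "ecgacgan_invalid_spec")
  expect_error(discriminator_spec(3, conv_layers = 4, channels = c(8, 8)),
               class = "ecgacgan_invalid_spec")
  s <- generator_spec(5, noise_len = 128L)
  expect_s3_class(s, "generator_spec")
  expect_equal(length(s$channels), 9)
})

test_that("an untrained generator meets its output contract", {
  spec <- generator_spec(3, noise_len = 64L)
  gen <- build_generator(spec, seed = 5)
  z <- matrix(rnorm(64 * 4), 64, 4)
  out <- generator_forward(gen, z, c(1L, 2L, 3L, 1L))$out
  expect_equal(dim(out), c(64L, 4L))
  expect_true(all(out >= -1 & out <= 1))
  out2 <- generator_forward(build_generator(spec, seed = 5), z,
                            c(1L, 2L, 3L, 1L))$out
  expect_identical(out, out2)
  expect_error(generator_forward(gen, z, c(1L, 2L, 4L, 1L)),
               class = "ecgacgan_invalid_argument")
})

test_that("the discriminator yields a source score and a class distribution", {
  spec <- discriminator_spec(4, input_len = 64L, channels = c(4, 4, 8, 8))
  disc <- build_discriminator(spec, seed = 9)
  x <- matrix(rnorm(64 * 7), 64, 7)
  fw <- discriminator_forward(disc, x)
  expect_equal(dim(fw$src), c(1L, 7L))
  probs <- discriminator_classify(disc, asplit(x, 2))
  expect_equal(dim(probs), c(7L, 4L))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(probs >= 0))
  expect_error(discriminator_forward(disc, matrix(rnorm(32 * 2), 32, 2)),
               class = "ecgacgan_invalid_argument")
})

tiny_cycle_set <- function(n_per_class = 24, len = 64) {
  study <- generate_study(2, sessions_per_subject = 1, duration_s = 30,
                          fs = 250, seed = 41, states = state_profiles()[1, ])
  cyc <- segment_cycles(study, segmentation_config(cycle_len = len),
                        peaks_col = "truth_r_peaks")
  cyc |>
    dplyr::group_by(subject_id) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
}

test_that("adversarial training is seeded, guarded and well-typed", {
  cyc <- tiny_cycle_set()
  gs <- generator_spec(2, noise_len = 64L)
  ds <- discriminator_spec(2, input_len = 64L)

  # zero epochs: untouched initialization, empty history
  fit0 <- train_acgan(cyc, gs, ds, gan_train_config(epochs = 0, seed = 2))
  expect_equal(nrow(fit0$history), 0)
  init <- build_generator(gs, seed = withr::with_seed(2, {
    sample.int(.Machine$integer.max, 1)
  }))
  expect_identical(fit0$generator$layers, init$layers)

  cfg <- gan_train_config(epochs = 3, batch_size = 16, seed = 2)
  fit_a <- train_acgan(cyc, gs, ds, cfg)
  fit_b <- train_acgan(cyc, gs, ds, cfg)
  expect_identical(fit_a$history, fit_b$history)
  expect_true(all(is.finite(as.matrix(fit_a$history[, -1]))))

  expect_error(train_acgan(cyc[cyc$subject_id == cyc$subject_id[1], ],
                           gs, ds, cfg),
               class = "ecgacgan_invalid_argument")
})

test_that("generated cycles carry the synthetic tag and a seeded stream", {
  cyc <- tiny_cycle_set()
  fit <- train_acgan(cyc, generator_spec(2, noise_len = 64L),
                     discriminator_spec(2, input_len = 64L),
                     gan_train_config(epochs = 2, batch_size = 16, seed = 2))
  g1 <- generate_cycles(fit, "S001", 5, seed = 8)
  g2 <- generate_cycles(fit, "S001", 5, seed = 8)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 5)
  expect_true(all(g1$source == "synthetic"))
  expect_true(all(purrr::map_int(g1$values, length) == 64))
  expect_error(generate_cycles(fit, "nope", 2, seed = 1),
               class = "ecgacgan_invalid_argument")
})

test_that("the trained toy generator separates its classes", {
  fit <- toy_gan_fit()
  cyc <- toy_cycles_3class()
  classes <- fit$class_levels

  # same noise, different class conditioning: different waveforms
  z <- withr::with_seed(3, matrix(rnorm(fit$cycle_len * 2), fit$cycle_len, 2))
  o <- generator_forward(fit$generator, z[, c(1, 1)], c(1L, 2L))$out
  expect_gt(sqrt(sum((o[, 1] - o[, 2])^2)), 0)

  # generated cycles are closer to their own class's mean real cycle
  tmpl <- lapply(classes, function(s) {
    v <- cyc$values[cyc$subject_id == s]
    Reduce(`+`, v) / length(v)
  })
  bank <- generate_cycle_bank(fit, n_per_class = 10, seed = 5)
  own_beats_other <- 0L; pairs <- 0L
  for (i in seq_along(classes)) {
    gen_i <- bank$values[bank$subject_id == classes[i]]
    cos_own <- mean(purrr::map_dbl(gen_i, cosine_similarity, b = tmpl[[i]]))
    for (j in seq_along(classes)[-i]) {
      cos_other <- mean(purrr::map_dbl(gen_i, cosine_similarity,
                                       b = tmpl[[j]]))
      own_beats_other <- own_beats_other + (cos_own > cos_other)
      pairs <- pairs + 1L
    }
  }
  expect_gte(own_beats_other / pairs, 0.9)
})

test_that("the auxiliary classifier masters held-out real cycles", {
  fit <- toy_gan_fit()
  held <- toy_heldout_cycles()
  probs <- discriminator_classify(fit, held$values)
  pred <- fit$class_levels[max.col(probs)]
  expect_gte(mean(pred == held$subject_id), 0.95)
})

test_that("adversarial training improves generation quality over epochs", {
  cyc <- toy_cycles_3class()
  early <- train_acgan(cyc, cfg = gan_train_config(epochs = 10, seed = 3))
  late <- toy_gan_fit()                      # same seed, 300 epochs
  score <- function(fit) {
    evaluate_generation(cyc, generate_cycle_bank(fit, 10, seed = 5),
                        seed = 1)$overall$mean_cosine
  }
  expect_gte(score(late), score(early))
})
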