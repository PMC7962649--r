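test_that("the faithful-mode member grid is enforced", {
  expect_error(member_config(epochs = 600), class = "ecgacgan_invalid_config")
  expect_error(member_config(batch_size = 100),
               class = "ecgacgan_invalid_config")
  expect_error(member_config(dropout = 0.8), class = "ecgacgan_invalid_config")
  expect_error(member_config(dropout = 0.45),
               class = "ecgacgan_invalid_config")
  expect_error(member_config(lr = 0.01), class = "ecgacgan_invalid_config")
  expect_s3_class(member_config(epochs = 750, batch_size = 512,
                                dropout = 0.7), "member_config")
  # the explicit flag lifts the grid
  free <- member_config(epochs = 20, batch_size = 16, dropout = 0.2,
                        lr = 0.01, faithful = FALSE)
  expect_s3_class(free, "member_config")

  grid <- member_grid()
  expect_length(grid, 6)
  expect_setequal(unique(purrr::map_int(grid, "epochs")), c(500L, 750L))
  expect_setequal(unique(purrr::map_int(grid, "batch_size")), c(256L, 512L))
  expect_setequal(unique(purrr::map_dbl(grid, "dropout")), c(0.5, 0.7))
})

fake_result <- function(id, acc, labels = rep(c("A", "B"), 5), p = 4) {
  structure(list(member_id = id, config = NULL, val_accuracy = acc,
                 fused_train = matrix(seq_len(length(labels) * p) + id,
                                      length(labels), p),
                 train_labels = labels, class_levels = c("A", "B"),
                 layers = NULL),
            class = "member_result")
}

test_that("top-3 selection sorts by accuracy with id tie-breaks", {
  res <- purrr::map2(1:5, c(0.90, 0.80, 0.95, 0.70, 0.85), fake_result)
  sel <- rank_and_select(res)
  expect_equal(purrr::map_int(sel, "member_id"), c(3L, 1L, 5L))

  tied <- purrr::map2(1:4, rep(0.8, 4), fake_result)
  expect_equal(purrr::map_int(rank_and_select(tied), "member_id"),
               c(1L, 2L, 3L))

  exactly3 <- purrr::map2(1:3, c(0.1, 0.2, 0.3), fake_result)
  expect_equal(purrr::map_int(rank_and_select(exactly3), "member_id"),
               c(3L, 2L, 1L))
  expect_error(rank_and_select(exactly3[1:2]),
               class = "ecgacgan_invalid_argument")
})

test_that("fusing concatenates aligned member outputs", {
  sel <- purrr::map2(1:3, c(0.9, 0.8, 0.7), fake_result)
  fused <- build_retraining_set(sel)
  expect_equal(dim(fused$x), c(10L, 12L))
  expect_equal(fused$x[, 1:4], sel[[1]]$fused_train)
  expect_equal(fused$labels, sel[[1]]$train_labels)

  bad <- sel
  bad[[2]]$train_labels <- rev(bad[[2]]$train_labels)
  expect_error(build_retraining_set(bad), class = "ecgacgan_invalid_argument")
  expect_error(build_retraining_set(sel[1:2]),
               class = "ecgacgan_invalid_argument")
})

test_that("a member trains deterministically and reports aligned outputs", {
  seqs <- tiny_sequences()
  sp <- split_sequences(seqs, seed = 4)
  cfg <- member_config(epochs = 10, batch_size = 16, dropout = 0.3,
                       faithful = FALSE, seed = 9)
  r1 <- train_member(sp$train, sp$val, cfg)
  r2 <- train_member(sp$train, sp$val, cfg)
  expect_identical(r1$val_accuracy, r2$val_accuracy)
  expect_identical(r1$fused_train, r2$fused_train)
  expect_equal(nrow(r1$fused_train), nrow(sp$train))
  expect_true(r1$val_accuracy >= 0 && r1$val_accuracy <= 1)

  solo <- sp$train[sp$train$subject_id == sp$train$subject_id[1], ]
  expect_error(train_member(solo, sp$val, cfg),
               class = "ecgacgan_invalid_argument")
})

test_that("the fused classifier recognizes its own training sequences", {
  seqs <- tiny_sequences()
  cfgs <- member_grid(epochs_opts = c(10L, 10L), batch_opts = c(16L, 32L),
                      faithful = FALSE, seed = 2)
  ens <- train_ensemble(seqs, cfgs, seed = 6)
  sp <- split_sequences(seqs, seed = 6)
  rec <- predict_ensemble(ens, sp$train)
  expect_gte(rec$accuracy, 0.9)
  expect_equal(nrow(rec$predictions), nrow(sp$train))
  expect_error(predict_ensemble(ens, sp$train[0, ]),
               class = "ecgacgan_invalid_argument")
  # determinism end to end
  ens2 <- train_ensemble(seqs, cfgs, seed = 6)
  expect_identical(tidy(ens), tidy(ens2))
  expect_identical(predict_ensemble(ens2, sp$train)$accuracy, rec$accuracy)
})

test_that("member order does not change fused recognition materially", {
  seqs <- tiny_sequences()
  cfgs <- member_grid(epochs_opts = c(10L, 10L), batch_opts = c(16L, 32L),
                      faithful = FALSE, seed = 2)
  ens <- train_ensemble(seqs, cfgs, seed = 6)
  sp <- split_sequences(seqs, seed = 6)
  acc1 <- predict_ensemble(ens, sp$train)$accuracy
  perm <- ens
  perm$selected <- perm$selected[c(2, 3, 1)]
  perm$fused <- build_retraining_set(perm$selected)
  acc2 <- predict_ensemble(perm, sp$train)$accuracy
  expect_lte(abs(acc1 - acc2), 0.02)
})

test_that("unseen comparison subjects are flagged and scored as errors", {
  seqs <- tiny_sequences()
  cfgs <- member_grid(epochs_opts = c(10L, 10L), batch_opts = c(16L, 32L),
                      faithful = FALSE, seed = 2)
  ens <- train_ensemble(seqs, cfgs, seed = 6)
  probe <- seqs[1:2, ]
  probe$subject_id <- "GHOST"
  expect_warning(rec <- predict_ensemble(ens, probe), "GHOST")
  expect_equal(rec$accuracy, 0)
})
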