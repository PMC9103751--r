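# Small corpora and model sizes keep these runs to a few seconds each.

train_fixture <- function(seed = 31L, n_records = 40L, noise = 0) {
  spec <- synthetic_spec(n_records = n_records, lexicon_size = 30L,
                         alphabet_size = 40L, n_class_words_per_class = 4L,
                         class_word_strength = 1, label_noise = noise,
                         sentence_length_words = c(2L, 6L), seed = seed)
  recs <- generate_corpus(spec)
  splits <- split_dataset(recs, seed = seed)
  vocab <- build_vocabulary(splits$train)
  mc <- joint_model_config(vocab$size, embedding_dim = 8L,
                           recurrent_hidden = 6L,
                           conv_kernel_widths = c(2L, 3L),
                           conv_channels_per_width = 4L,
                           dropout = 0.1, seed = seed)
  list(splits = splits, vocab = vocab, mc = mc)
}

test_that("fixed-seed training reproduces epoch-1 losses bit for bit", {
  f <- train_fixture()
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 5L)
  r1 <- train_joint(f$splits, f$vocab, f$mc, tc)
  r2 <- train_joint(f$splits, f$vocab, f$mc, tc)
  expect_identical(r1$log$L0, r2$log$L0)
  expect_identical(r1$log$L1, r2$log$L1)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("the restored checkpoint reproduces the logged best validation loss", {
  f <- train_fixture(seed = 37L)
  tc <- train_config(epochs = 4L, batch_size = 8L, seed = 6L)
  run <- train_joint(f$splits, f$vocab, f$mc, tc)
  expect_identical(run$best_val_loss, min(run$log$val_loss))
  expect_identical(run$best_epoch, which.min(run$log$val_loss))
  # recompute the validation joint loss from the restored parameters
  vl <- jointcws:::validation_losses(run$model, f$splits$val, 8L)
  expect_equal(joint_loss(vl$L0, vl$L1, run$state), run$best_val_loss,
               tolerance = 1e-10)
})

test_that("training aborts with a diagnostic on divergence", {
  f <- train_fixture(seed = 41L)
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 7L,
                     learning_rate = Inf, clip_norm = 0)
  expect_error(train_joint(f$splits, f$vocab, f$mc, tc),
               "diverged|non-finite")
})

test_that("a zero classification weight keeps the classifier at chance while tagging trains", {
  f <- train_fixture(seed = 43L, n_records = 60L)
  tc <- train_config(epochs = 6L, batch_size = 8L, seed = 8L,
                     strategy = "fixed", fixed_weights = c(1, 0))
  run <- train_joint(f$splits, f$vocab, f$mc, tc)
  # tagging trains: its validation loss decreases from epoch 1
  expect_lt(min(run$log$val_L0), run$log$val_L0[1L])
  # the classification head receives zero gradient: its parameters stay
  # at initialization
  init <- init_joint_model(f$mc, f$vocab)
  for (nm in grep("^(conv|cls)", names(init$params), value = TRUE))
    expect_identical(run$model$params[[nm]], init$params[[nm]])
})

test_that("the two-stage baseline feeds stage-1 predictions (not gold) to stage 2", {
  f <- train_fixture(seed = 47L)
  tc <- train_config(epochs = 2L, batch_size = 8L, seed = 9L)
  run <- train_two_stage(f$splits, f$vocab, f$mc, tc)
  expect_identical(run$feature_passes_per_sentence, 2L)
  # the stage-2 model consumes a boundary channel
  expect_identical(run$model$config$heads, "cls")
  expect_gt(run$model$config$boundary_dim, 0L)
  # stage-1 predictions at this scale are imperfect, so the boundary
  # channel must differ from gold somewhere across the test split
  tags <- jointcws:::predict_tags_int(run$stage1$model, f$splits$test)
  gold <- lapply(f$splits$test, function(r)
    unname(c(B = 1L, I = 2L, O = 3L)[r$tags]))
  expect_false(identical(tags, gold))
  # and the stage-2 batches carry exactly the stage-1 predictions
  with_pred <- Map(function(r, tg) { r$pred_tags <- tg; r },
                   f$splits$test, tags)
  bt <- make_batches(with_pred, f$vocab, batch_size = 64L)[[1L]]
  expect_identical(bt$boundary[1L, seq_len(sum(bt$mask[1L, ]))],
                   tags[[bt$record_ids[1L]]])
})

test_that("joint and two-stage runs report the documented feature-pass counts", {
  f <- train_fixture(seed = 53L)
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 10L)
  expect_identical(train_joint(f$splits, f$vocab, f$mc, tc)$feature_passes_per_sentence,
                   1L)
})

test_that("dynamic strategies run end to end and log their weights", {
  f <- train_fixture(seed = 59L)
  for (strat in c("gradnorm", "dwa", "uncertainty")) {
    tc <- train_config(epochs = 3L, batch_size = 8L, seed = 11L,
                       strategy = strat)
    run <- train_joint(f$splits, f$vocab, f$mc, tc)
    expect_identical(nrow(run$log), 3L)
    expect_true(all(is.finite(run$log$r0)), info = strat)
    expect_true(all(run$log$r0 > 0), info = strat)
    if (strat %in% c("gradnorm", "dwa"))
      expect_equal(run$log$r0 + run$log$r1, rep(2, 3L), tolerance = 1e-9,
                   info = strat)
  }
})

test_that("grid search evaluates every weight pair and picks by validation accuracy", {
  f <- train_fixture(seed = 67L)
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 14L)
  gs <- grid_search_weights(f$splits, f$vocab, f$mc, tc, grid = c(0.2, 0.4))
  expect_identical(nrow(gs$results), 4L)
  expect_true(all(is.finite(gs$results$val_class_accuracy)))
  best_row <- which.max(gs$results$val_class_accuracy)
  expect_identical(gs$best,
                   c(gs$results$r0[best_row], gs$results$r1[best_row]))
  expect_identical(gs$run$best_val_class_accuracy,
                   max(gs$results$val_class_accuracy))
})

test_that("cross-validation aggregates per-fold metrics with distinct seeds", {
  spec <- synthetic_spec(n_records = 40L, lexicon_size = 30L,
                         alphabet_size = 40L, n_class_words_per_class = 4L,
                         sentence_length_words = c(2L, 5L), seed = 61L)
  recs <- generate_corpus(spec)
  tc <- train_config(epochs = 1L, batch_size = 8L, seed = 12L, folds = 2L)
  cv <- run_cross_validation(
    recs,
    function(v) joint_model_config(v, embedding_dim = 6L,
                                   recurrent_hidden = 4L,
                                   conv_kernel_widths = c(2L, 3L),
                                   conv_channels_per_width = 3L,
                                   seed = 13L),
    tc)
  expect_identical(nrow(cv$per_fold), 2L)
  expect_identical(anyDuplicated(cv$per_fold$seed), 0L)
  expect_equal(cv$summary$mean[cv$summary$metric == "class_accuracy"],
               mean(cv$per_fold$class_accuracy), tolerance = 1e-12)
  expect_error(run_cross_validation(recs, identity,
                                    train_config(folds = 1L)),
               "folds")
})
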