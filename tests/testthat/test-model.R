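test_that("forward output shapes track the batch and config", {
  s <- tiny_setup(seed = 4L)
  bt <- make_batches(s$records, s$vocab, batch_size = 8L)[[1L]]
  fwd <- model_forward(s$model, bt)
  B <- nrow(bt$indices); Tn <- ncol(bt$indices)
  expect_identical(dim(fwd$tag_scores), c(B * Tn, 3L))
  expect_identical(dim(fwd$class_scores), c(B, 2L))
  expect_true(all(is.finite(fwd$tag_scores)))
  expect_true(all(is.finite(fwd$class_scores)))
  # single-character input produces one scored position
  one <- list(annotated_record("x", 0L))
  b1 <- make_batches(one, s$vocab, batch_size = 1L)[[1L]]
  f1 <- model_forward(s$model, b1)
  expect_identical(dim(f1$tag_scores), c(1L, 3L))
})

test_that("padding embeds to exact zeros and equal indices share vectors", {
  s <- tiny_setup(seed = 6L)
  expect_identical(s$model$params$emb[s$vocab$pad_index, ],
                   rep(0, s$config$embedding_dim))
  idx <- chars_to_indices(s$records[[1L]]$chars, s$vocab)
  expect_identical(s$model$params$emb[idx[1L], ], s$model$params$emb[idx[1L], ])
  expect_error(
    model_forward(s$model, list(indices = matrix(s$vocab$size + 5L, 1, 1),
                                mask = matrix(TRUE, 1, 1))),
    "out of range")
})

test_that("forward passes are deterministic with dropout disabled", {
  s <- tiny_setup(seed = 8L, dropout = 0)
  bt <- make_batches(s$records, s$vocab, batch_size = 8L)[[1L]]
  f1 <- model_forward(s$model, bt)
  f2 <- model_forward(s$model, bt)
  expect_identical(f1$tag_scores, f2$tag_scores)
  expect_identical(f1$class_scores, f2$class_scores)
})

test_that("analytic parameter count matches the actual parameter arrays", {
  for (args in list(list(), list(heads = "seg"),
                    list(heads = "cls", boundary_dim = 8L),
                    list(embedding_dim = 7L, recurrent_hidden = 3L,
                         conv_kernel_widths = c(2L, 4L),
                         conv_channels_per_width = 5L))) {
    s <- do.call(tiny_setup, c(list(seed = 10L), args))
    expect_identical(count_parameters(s$config),
                     as.integer(sum(vapply(s$model$params, length, numeric(1L)))))
  }
})

test_that("masked max-pooling is invariant to appending padding", {
  s <- tiny_setup(seed = 12L, heads = "cls")
  bt <- make_batches(s$records[1:4], s$vocab, batch_size = 4L)[[1L]]
  fwd <- model_forward(s$model, bt)
  pad_cols <- 5L
  bt2 <- bt
  bt2$indices <- cbind(bt$indices,
                       matrix(s$vocab$pad_index, nrow(bt$indices), pad_cols))
  bt2$tag_targets <- cbind(bt$tag_targets, matrix(0L, nrow(bt$mask), pad_cols))
  bt2$mask <- cbind(bt$mask, matrix(FALSE, nrow(bt$mask), pad_cols))
  fwd2 <- model_forward(s$model, bt2)
  expect_equal(fwd$class_scores, fwd2$class_scores, tolerance = 1e-12)
})

test_that("duplicating the max-activating window leaves pooled features unchanged", {
  # construct a record, find its scores, then repeat the whole sentence:
  # max-pooling keeps the same maxima
  s <- tiny_setup(seed = 14L, heads = "cls")
  r <- s$records[[1L]]
  rep_r <- annotated_record(c(r$words, r$words), r$label)
  b1 <- make_batches(list(r), s$vocab, batch_size = 1L)[[1L]]
  b2 <- make_batches(list(rep_r), s$vocab, batch_size = 1L)[[1L]]
  f1 <- model_forward(s$model, b1)
  f2 <- model_forward(s$model, b2)
  # every window of the single sentence exists in the doubled one, so the
  # pooled maxima (hence scores) can only come from the same activations
  # produced by a full copy of the sentence; scores must agree whenever
  # no cross-boundary window dominates -- check the pooled pathway via
  # class scores computed from identical maxima
  p <- s$model$params
  pool_of <- function(bt) {
    fwd <- model_forward(s$model, bt)
    fwd$cache$pooled_d
  }
  expect_true(all(pool_of(b2) >= pool_of(b1) - 1e-12))
})

test_that("an all-padding row warns and still yields finite scores", {
  s <- tiny_setup(seed = 16L, heads = "cls")
  bt <- list(indices = matrix(s$vocab$pad_index, 1L, 4L),
             tag_targets = matrix(0L, 1L, 4L),
             labels = 0L,
             mask = matrix(FALSE, 1L, 4L))
  expect_warning(fwd <- model_forward(s$model, bt), "padding")
  expect_true(all(is.finite(fwd$class_scores)))
})

test_that("argmax tags always decode to a total segmentation", {
  s <- tiny_setup(seed = 18L)
  preds <- predict(s$model, s$records)
  for (i in seq_along(preds)) {
    expect_identical(paste0(preds[[i]]$words, collapse = ""),
                     paste0(s$records[[i]]$chars, collapse = ""))
    expect_true(preds[[i]]$label %in% c(0L, 1L))
    expect_gte(preds[[i]]$prob, 0.5)
    expect_lte(preds[[i]]$prob, 1)
    expect_equal(preds[[i]]$prob,
                 max(preds[[i]]$score, 1 - preds[[i]]$score),
                 tolerance = 1e-12)
  }
  # prediction is deterministic in evaluation mode
  p2 <- predict(s$model, s$records)
  expect_identical(preds, p2)
  expect_error(predict(s$model, ""), "empty")
})

test_that("backpropagation matches finite differences on every parameter", {
  s <- tiny_setup(seed = 20L, n_records = 8L)
  bt <- make_batches(s$records, s$vocab, batch_size = 8L)[[1L]]
  w <- c(0.7, 1.3)
  loss_at <- function(params) {
    m <- s$model; m$params <- params
    fwd <- model_forward(m, bt)
    w[1L] * masked_tag_loss(fwd$tag_scores, bt$tag_targets, bt$mask) +
      w[2L] * class_loss(fwd$class_scores, bt$labels)
  }
  fwd <- model_forward(s$model, bt)
  tl <- masked_tag_loss(fwd$tag_scores, bt$tag_targets, bt$mask, with_grad = TRUE)
  cl <- class_loss(fwd$class_scores, bt$labels, with_grad = TRUE)
  gr <- model_backward(s$model, bt, fwd, tl$grad, cl$grad)
  comb <- jointcws:::combine_task_grads(gr$seg, gr$cls, w)
  eps <- 1e-5
  set.seed(99)
  for (nm in names(comb)) {
    p <- s$model$params[[nm]]
    for (i in sample(length(p), min(6L, length(p)))) {
      # the padding embedding row is frozen: analytic gradient is 0 there
      if (nm == "emb" && (i - 1L) %% nrow(p) + 1L == s$vocab$pad_index) next
      pp <- s$model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- s$model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(comb[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("compiled LSTM kernels match the plain-R reference recurrence", {
  set.seed(333)
  B <- 3L; Tn <- 5L; D <- 4L; H <- 3L
  Xt <- lapply(seq_len(Tn), function(t) matrix(rnorm(B * D), B, D))
  Xstack <- do.call(rbind, Xt)
  maskN <- matrix(1, B, Tn)
  maskN[1L, 4:5] <- 0; maskN[2L, 5L] <- 0   # right padding
  Wx <- matrix(rnorm(D * 4L * H, sd = 0.3), D, 4L * H)
  Wh <- matrix(rnorm(H * 4L * H, sd = 0.3), H, 4L * H)
  b <- rnorm(4L * H, sd = 0.1)
  for (rev in c(FALSE, TRUE)) {
    rf <- jointcws:::run_lstm_direction(Xt, maskN, Wx, Wh, b, reverse = rev)
    cf <- jointcws:::lstm_forward_cpp(Xstack, maskN, Wx, Wh, b, rev)
    expect_equal(do.call(rbind, rf$H), cf$H, tolerance = 1e-12)
    dH <- lapply(seq_len(Tn), function(t) matrix(rnorm(B * H), B, H))
    rb <- jointcws:::run_lstm_direction_backward(rf, Xt, dH, Wx, Wh)
    cb <- jointcws:::lstm_backward_cpp(Xstack, maskN, Wx, Wh, cf$H, cf$gates,
                                       cf$cnew, do.call(rbind, dH), rev)
    expect_equal(rb$Wx, cb$Wx, tolerance = 1e-12)
    expect_equal(rb$Wh, cb$Wh, tolerance = 1e-12)
    expect_equal(rb$b, as.numeric(cb$b), tolerance = 1e-12)
    expect_equal(do.call(rbind, rb$dX), cb$dX, tolerance = 1e-12)
  }
})

test_that("checkpoints round-trip the model and verify the vocabulary hash", {
  s <- tiny_setup(seed = 22L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(s$model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, s$model$params)
  expect_identical(back$config, s$model$config)
  bt <- make_batches(s$records, s$vocab, batch_size = 4L)[[1L]]
  expect_identical(model_forward(back, bt)$class_scores,
                   model_forward(s$model, bt)$class_scores)
})
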