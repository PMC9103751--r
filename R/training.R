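#' Training configuration
#'
#' Optimization protocol for the joint model and the baselines: Adam,
#' learning rate 0.001, 50 epochs, the model checkpointed at the epoch
#' with the minimum validation (joint) loss.
#'
#' @param epochs number of training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param strategy loss-weighting strategy key (see [weight_state()]).
#' @param fixed_weights `c(r0, r1)` used by the fixed strategy
#'   (default `c(0.4, 0.4)`).
#' @param folds number of cross-validation repeats for
#'   [run_cross_validation()].
#' @param seed integer seed governing initialization, shuffling and
#'   dropout.
#' @param mode `"joint"`, `"two_stage"` or `"classification_only"`.
#' @param clip_norm global gradient-norm clip (0 disables).
#' @param alpha,temperature,gradnorm_lr strategy hyperparameters passed to
#'   [weight_state()].
#' @param checkpoint_dir directory for checkpoint files, or `NULL` to
#'   keep the best model in memory only.
#' @param verbose print per-epoch progress.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.001,
                         batch_size = 32L,
                         strategy = c("fixed", "gradnorm", "dwa", "uncertainty"),
                         fixed_weights = c(0.4, 0.4),
                         folds = 7L, seed = 1L,
                         mode = c("joint", "two_stage", "classification_only"),
                         clip_norm = 5, alpha = 1.5, temperature = 2,
                         gradnorm_lr = 0.025,
                         checkpoint_dir = NULL, verbose = FALSE) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), strategy = strategy,
         fixed_weights = fixed_weights, folds = as.integer(folds),
         seed = as.integer(seed), mode = mode, clip_norm = clip_norm,
         alpha = alpha, temperature = temperature, gradnorm_lr = gradnorm_lr,
         checkpoint_dir = checkpoint_dir, verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

# ---------------------------------------------------------------------------
# Adam optimizer over a named list of parameter arrays.

adam_init <- function(params) {
  zeros <- lapply(params, function(x) x * 0)  # keeps each array's shape
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1L))))
}

# Combine per-task gradient lists with task weights.  Parameters present
# in both tasks (the shared embedding) receive the weighted sum.
combine_task_grads <- function(seg, cls, w) {
  out <- list()
  for (nm in names(seg)) out[[nm]] <- w[1L] * seg[[nm]]
  for (nm in names(cls)) {
    out[[nm]] <- if (is.null(out[[nm]])) w[2L] * cls[[nm]]
                 else out[[nm]] + w[2L] * cls[[nm]]
  }
  out
}

# ---------------------------------------------------------------------------

# Forward the model over a record set in evaluation mode, collecting
# per-record predicted tags (integer codes), predicted labels and class-1
# scores alongside the gold values.
collect_predictions <- function(model, records, batch_size = 64L) {
  cfg <- model$config
  batches <- make_batches(records, model$vocab, batch_size = batch_size,
                          shuffle_seed = NULL, bucket_by_length = TRUE)
  n <- length(records)
  pred_tags <- vector("list", n)
  gold_tags <- vector("list", n)
  pred_label <- rep(NA_integer_, n)
  score1 <- rep(NA_real_, n)
  labels <- vapply(records, `[[`, integer(1L), "label")
  for (bt in batches) {
    fwd <- model_forward(model, bt, train = FALSE)
    B <- nrow(bt$indices)
    probs <- if (!is.null(fwd$class_scores)) softmax_rows(fwd$class_scores)
    for (b in seq_len(B)) {
      id <- bt$record_ids[[b]]
      L <- sum(bt$mask[b, ])
      if (!is.null(fwd$tag_scores)) {
        rows <- (seq_len(L) - 1L) * B + b
        pred_tags[[id]] <- max.col(fwd$tag_scores[rows, , drop = FALSE],
                                   ties.method = "first")
      }
      gold_tags[[id]] <- bt$tag_targets[b, seq_len(L)]
      if (!is.null(probs)) {
        pred_label[[id]] <- which.max(probs[b, ]) - 1L
        score1[[id]] <- probs[b, 2L]
      }
    }
  }
  list(gold_tags = gold_tags, pred_tags = pred_tags, labels = labels,
       pred_label = pred_label, score = score1)
}

# Validation losses in evaluation mode (no dropout).
validation_losses <- function(model, records, batch_size) {
  batches <- make_batches(records, model$vocab, batch_size = batch_size,
                          shuffle_seed = NULL, bucket_by_length = TRUE)
  L0s <- c(); L1s <- c(); w0 <- c(); w1 <- c()
  for (bt in batches) {
    fwd <- model_forward(model, bt, train = FALSE)
    nb <- nrow(bt$indices)
    if (!is.null(fwd$tag_scores)) {
      L0s <- c(L0s, masked_tag_loss(fwd$tag_scores, bt$tag_targets, bt$mask))
      w0 <- c(w0, sum(bt$mask))
    }
    if (!is.null(fwd$class_scores)) {
      L1s <- c(L1s, class_loss(fwd$class_scores, bt$labels))
      w1 <- c(w1, nb)
    }
  }
  list(L0 = if (length(L0s)) sum(L0s * w0) / sum(w0) else NA_real_,
       L1 = if (length(L1s)) sum(L1s * w1) / sum(w1) else NA_real_)
}

# Core epoch loop shared by the joint model, the two-stage stages and the
# classification-only baseline.  `tasks` names the objectives actually
# trained; the model's heads must cover them.
train_network <- function(splits, vocab, model_config, tc,
                          tasks = c("seg", "cls"),
                          state = NULL, run_label = "joint") {
  has_seg <- "seg" %in% tasks
  has_cls <- "cls" %in% tasks
  model <- init_joint_model(model_config, vocab)
  opt <- adam_init(model$params)
  if (is.null(state)) {
    state <- weight_state(tc$strategy,
                          r0 = if (tc$strategy == "fixed") tc$fixed_weights[1L] else 1,
                          r1 = if (tc$strategy == "fixed") tc$fixed_weights[2L] else 1,
                          alpha = tc$alpha, temperature = tc$temperature,
                          gradnorm_lr = tc$gradnorm_lr)
  }
  sig_opt <- list(m = c(0, 0), v = c(0, 0), t = 0L)  # adam slots for log-sigmas
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_,
               val_class_accuracy = NA_real_, val_tag_accuracy = NA_real_)
  log <- vector("list", tc$epochs)
  clip_events <- 0L
  for (epoch in seq_len(tc$epochs)) {
    batches <- make_batches(splits$train, vocab, tc$batch_size,
                            shuffle_seed = derive_seed(tc$seed, 1000L + epoch),
                            bucket_by_length = TRUE)
    eL0 <- c(); eL1 <- c()
    with_local_seed(derive_seed(tc$seed, 2000L + epoch), {
      for (bt in batches) {
        fwd <- model_forward(model, bt, train = TRUE)
        L0 <- NA_real_; L1 <- NA_real_
        d_tag <- NULL; d_cls <- NULL
        if (has_seg) {
          tl <- masked_tag_loss(fwd$tag_scores, bt$tag_targets, bt$mask,
                                with_grad = TRUE)
          L0 <- tl$loss; d_tag <- tl$grad
        }
        if (has_cls) {
          cl <- class_loss(fwd$class_scores, bt$labels, with_grad = TRUE)
          L1 <- cl$loss; d_cls <- cl$grad
        }
        grads <- model_backward(model, bt, fwd, d_tag, d_cls)
        if (has_seg && has_cls) {
          w <- effective_weights(state)
          jl <- joint_loss(L0, L1, state)
          combined <- combine_task_grads(grads$seg, grads$cls, w)
        } else if (has_seg) {
          jl <- L0
          combined <- grads$seg
        } else {
          jl <- L1
          combined <- grads$cls
        }
        if (!is.finite(jl))
          stop(sprintf("%s training diverged (non-finite loss) at epoch %d",
                       run_label, epoch))
        if (tc$clip_norm > 0) {
          gn <- grad_global_norm(combined)
          if (gn > tc$clip_norm) {
            combined <- lapply(combined, function(g) g * tc$clip_norm / gn)
            clip_events <- clip_events + 1L
          }
        }
        st <- adam_step(model$params, combined, opt, tc$learning_rate)
        model$params <- st$params
        opt <- st$opt
        if (has_seg && has_cls) {
          if (state$strategy == "gradnorm") {
            g0 <- sqrt(sum(grads$seg$emb^2))
            g1 <- sqrt(sum(grads$cls$emb^2))
            state <- update_weights_gradnorm(state, c(L0, L1), c(g0, g1))
          } else if (state$strategy == "uncertainty") {
            g <- uncertainty_log_sigma_grad(state, c(L0, L1))
            sig_opt$t <- sig_opt$t + 1L
            sig_opt$m <- 0.9 * sig_opt$m + 0.1 * g
            sig_opt$v <- 0.999 * sig_opt$v + 0.001 * g * g
            state$log_sigma <- state$log_sigma -
              tc$learning_rate * (sig_opt$m / (1 - 0.9^sig_opt$t)) /
              (sqrt(sig_opt$v / (1 - 0.999^sig_opt$t)) + 1e-8)
          }
        }
        eL0 <- c(eL0, L0); eL1 <- c(eL1, L1)
      }
    })
    if (has_seg && has_cls && state$strategy == "dwa")
      state <- update_weights_dwa(state, c(mean(eL0), mean(eL1)))
    vl <- validation_losses(model, splits$val, tc$batch_size)
    val_joint <- if (has_seg && has_cls) joint_loss(vl$L0, vl$L1, state)
                 else if (has_seg) vl$L0 else vl$L1
    vp <- collect_predictions(model, splits$val)
    val_tag_acc <- if (has_seg)
      mean(unlist(vp$pred_tags) == unlist(vp$gold_tags)) else NA_real_
    val_cls_acc <- if (has_cls) mean(vp$pred_label == vp$labels) else NA_real_
    w <- effective_weights(state)
    log[[epoch]] <- data.frame(
      epoch = epoch, L0 = mean(eL0), L1 = mean(eL1),
      r0 = w[1L], r1 = w[2L],
      val_L0 = vl$L0, val_L1 = vl$L1, val_loss = val_joint,
      val_tag_accuracy = val_tag_acc, val_class_accuracy = val_cls_acc)
    if (tc$verbose)
      message(sprintf("[%s] epoch %d: loss=%.4f val=%.4f", run_label, epoch,
                      mean(c(eL0, eL1), na.rm = TRUE), val_joint))
    if (val_joint < best$loss) {
      best$loss <- val_joint
      best$params <- model$params
      best$epoch <- epoch
      best$val_class_accuracy <- val_cls_acc
      best$val_tag_accuracy <- val_tag_acc
    }
  }
  model$params <- best$params
  list(model = model, state = state, log = do.call(rbind, log),
       best_epoch = best$epoch, best_val_loss = best$loss,
       best_val_class_accuracy = best$val_class_accuracy,
       best_val_tag_accuracy = best$val_tag_accuracy,
       clip_events = clip_events)
}

# Test-set evaluation of a trained model.
evaluate_on <- function(model, records) {
  pr <- collect_predictions(model, records)
  out <- list()
  if (!all(vapply(pr$pred_tags, is.null, logical(1L)))) {
    out$segmentation <- segmentation_metrics(pr$gold_tags, pr$pred_tags)
  }
  if (!all(is.na(pr$pred_label))) {
    out$classification <- classification_metrics(pr$labels, pr$pred_label)
    roc <- try(roc_auc(pr$labels, pr$score), silent = TRUE)
    if (!inherits(roc, "try-error")) {
      out$classification$roc_points <- roc$roc_points
      out$classification$auc <- roc$auc
    }
    out$predictions <- data.frame(label = pr$labels,
                                  predicted = pr$pred_label,
                                  score = pr$score)
  }
  out
}

#' Train the joint multi-task model
#'
#' One optimizer step per mini-batch: forward both heads, compute the
#' masked tagging loss and the classification loss, combine them with the
#' configured weighting strategy, backpropagate once through the shared
#' trunk.  Gradnorm and uncertainty weights update per step, dynamic
#' weight averaging per epoch.  The parameters from the epoch with the
#' lowest validation joint loss are restored before test evaluation.
#'
#' @param splits list with `train`, `val`, `test` record sets (see
#'   [split_dataset()]).
#' @param vocab a `jcs_vocabulary` built from the training split.
#' @param model_config a [joint_model_config()] with both heads.
#' @param tc a [train_config()].
#' @return a run result: `model`, per-epoch `log` (losses, weights,
#'   validation metrics), `best_epoch`, `best_val_loss`, `test_report`
#'   (segmentation and classification [classification_metrics()] /
#'   [segmentation_metrics()] reports plus per-record predictions),
#'   `feature_passes_per_sentence` (1 for the joint model) and
#'   `clip_events`.
#' @export
train_joint <- function(splits, vocab, model_config, tc) {
  run <- train_network(splits, vocab, model_config, tc,
                       tasks = c("seg", "cls"), run_label = "joint")
  run$test_report <- evaluate_on(run$model, splits$test)
  run$feature_passes_per_sentence <- 1L
  if (!is.null(tc$checkpoint_dir)) {
    dir.create(tc$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    run$checkpoint_path <- file.path(tc$checkpoint_dir, "joint_best.rds")
    save_checkpoint(run$model, run$checkpoint_path)
  }
  run
}

# Predicted integer tags (1=B, 2=I, 3=O) for every record.
predict_tags_int <- function(model, records) {
  collect_predictions(model, records)$pred_tags
}

#' Train the non-joint two-stage baseline
#'
#' Stage 1 trains a standalone Bi-LSTM tagger (segmentation loss only,
#' checkpointed on validation tagging loss).  Its *predicted* tags on
#' train, validation and test alike are then embedded (a learned 8-dim
#' boundary-tag embedding appended to the character embedding) as input
#' to stage 2, a standalone TextCNN classifier.  No gradient flows
#' between the stages, and each sentence undergoes feature extraction
#' twice — the efficiency cost the joint model avoids.
#'
#' @inheritParams train_joint
#' @param boundary_dim dimension of the stage-2 boundary-tag embedding.
#' @return a run result as in [train_joint()], with
#'   `feature_passes_per_sentence = 2`, `stage1` (the tagger's run) and
#'   the test report combining stage-1 segmentation metrics with stage-2
#'   classification metrics.
#' @export
train_two_stage <- function(splits, vocab, model_config, tc,
                            boundary_dim = 8L) {
  cfg1 <- model_config
  cfg1$heads <- "seg"
  cfg1$seed <- derive_seed(tc$seed, 11L)
  tc1 <- tc
  stage1 <- train_network(splits, vocab, cfg1, tc1, tasks = "seg",
                          run_label = "two_stage/seg")
  # re-represent every split with stage-1 predicted segmentations
  with_pred <- lapply(splits, function(recs) {
    tags <- predict_tags_int(stage1$model, recs)
    Map(function(r, tg) { r$pred_tags <- tg; r }, recs, tags)
  })
  cfg2 <- model_config
  cfg2$heads <- "cls"
  cfg2$boundary_dim <- as.integer(boundary_dim)
  cfg2$seed <- derive_seed(tc$seed, 12L)
  tc2 <- tc
  tc2$seed <- derive_seed(tc$seed, 13L)
  stage2 <- train_network(with_pred, vocab, cfg2, tc2, tasks = "cls",
                          run_label = "two_stage/cls")
  test_report <- evaluate_on(stage2$model, with_pred$test)
  seg_report <- evaluate_on(stage1$model, splits$test)
  test_report$segmentation <- seg_report$segmentation
  run <- list(model = stage2$model, stage1 = stage1,
              log = stage2$log, best_epoch = stage2$best_epoch,
              best_val_loss = stage2$best_val_loss,
              best_val_class_accuracy = stage2$best_val_class_accuracy,
              test_report = test_report,
              feature_passes_per_sentence = 2L,
              clip_events = stage1$clip_events + stage2$clip_events)
  if (!is.null(tc$checkpoint_dir)) {
    dir.create(tc$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    run$checkpoint_path <- file.path(tc$checkpoint_dir, "two_stage_best.rds")
    save_checkpoint(run$model, run$checkpoint_path)
    save_checkpoint(stage1$model,
                    file.path(tc$checkpoint_dir, "two_stage_stage1.rds"))
  }
  run
}

#' Train the one-stage classification-only baseline
#'
#' A TextCNN over raw character embeddings with no segmentation signal.
#'
#' @inheritParams train_joint
#' @return a run result as in [train_joint()].
#' @export
train_classification_only <- function(splits, vocab, model_config, tc) {
  cfg <- model_config
  cfg$heads <- "cls"
  cfg$boundary_dim <- 0L
  run <- train_network(splits, vocab, cfg, tc, tasks = "cls",
                       run_label = "classification_only")
  run$test_report <- evaluate_on(run$model, splits$test)
  run$feature_passes_per_sentence <- 1L
  run
}

# Dispatch on tc$mode.
train_mode <- function(splits, vocab, model_config, tc) {
  switch(tc$mode,
         joint = train_joint(splits, vocab, model_config, tc),
         two_stage = train_two_stage(splits, vocab, model_config, tc),
         classification_only =
           train_classification_only(splits, vocab, model_config, tc))
}

#' Repeated reseeded cross-validation
#'
#' Repeats split/train/test `folds` times with distinct derived seeds and
#' aggregates the test metrics.  (A fixed 60/10/30 split is incompatible
#' with literal k-fold partitioning, so "seven-fold cross-validation" is
#' realized as seven independently reseeded splits whose metrics are
#' averaged; the per-fold seeds are logged.)
#'
#' @param records the full corpus.
#' @param model_config_fn function(vocab_size) returning a
#'   [joint_model_config()]; called per fold because each fold's
#'   vocabulary is built from its own training split.
#' @param tc a [train_config()]; `tc$folds` controls the repeat count and
#'   `tc$mode` the model trained.
#' @return list with `per_fold` (data frame: fold, seed, metrics) and
#'   `summary` (mean and sd per metric).
#' @export
run_cross_validation <- function(records, model_config_fn, tc) {
  if (tc$folds < 2L) stop("run_cross_validation: folds must be >= 2")
  rows <- vector("list", tc$folds)
  for (k in seq_len(tc$folds)) {
    fold_seed <- derive_seed(tc$seed, 100L + k)
    splits <- split_dataset(records, seed = fold_seed)
    vocab <- build_vocabulary(splits$train)
    mc <- model_config_fn(vocab$size)
    tck <- tc
    tck$seed <- fold_seed
    run <- train_mode(splits, vocab, mc, tck)
    tr <- run$test_report
    rows[[k]] <- data.frame(
      fold = k, seed = fold_seed,
      seg_accuracy = tr$segmentation$accuracy %||% NA_real_,
      class_accuracy = tr$classification$accuracy %||% NA_real_,
      class_specificity = tr$classification$specificity %||% NA_real_,
      class_sensitivity = tr$classification$sensitivity %||% NA_real_,
      auc = tr$classification$auc %||% NA_real_)
  }
  per_fold <- do.call(rbind, rows)
  metrics <- setdiff(names(per_fold), c("fold", "seed"))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]), numeric(1L)),
    row.names = NULL)
  list(per_fold = per_fold, summary = summary)
}
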