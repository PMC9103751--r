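#' Joint model configuration
#'
#' Architecture hyperparameters for the joint segmentation/classification
#' network: a character-embedding trunk shared by a bidirectional LSTM
#' tagging head (3 BIO tag scores per character) and a multi-kernel
#' convolutional classification head (2 class scores per sentence,
#' kernel widths 3 and 5 by default, max-pooled over valid positions).
#'
#' @param vocab_size number of embedding rows (including padding and
#'   unknown).
#' @param embedding_dim character embedding dimension.
#' @param recurrent_hidden LSTM hidden units per direction.
#' @param conv_kernel_widths integer vector of convolution widths.
#' @param conv_channels_per_width output channels per kernel width.
#' @param dropout dropout probability applied to the tag-head input and
#'   the pooled classification features during training.
#' @param heads which heads the model carries: `"seg"`, `"cls"`, or both.
#' @param boundary_dim dimension of the learned word-boundary-tag
#'   embedding appended to character embeddings for the classification
#'   head (used by the two-stage baseline's second stage; 0 disables it).
#' @param seed seed for weight initialization.
#' @return An object of class `joint_model_config`.  `n_tags` is fixed at
#'   3 (B/I/O) and `n_classes` at 2.
#' @export
joint_model_config <- function(vocab_size,
                               embedding_dim = 128L,
                               recurrent_hidden = 128L,
                               conv_kernel_widths = c(3L, 5L),
                               conv_channels_per_width = 100L,
                               dropout = 0.1,
                               heads = c("seg", "cls"),
                               boundary_dim = 0L,
                               seed = 1L) {
  heads <- match.arg(heads, c("seg", "cls"), several.ok = TRUE)
  if (any(conv_kernel_widths < 1L)) stop("kernel widths must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(
    list(vocab_size = as.integer(vocab_size),
         embedding_dim = as.integer(embedding_dim),
         recurrent_hidden = as.integer(recurrent_hidden),
         conv_kernel_widths = as.integer(conv_kernel_widths),
         conv_channels_per_width = as.integer(conv_channels_per_width),
         n_tags = 3L, n_classes = 2L,
         dropout = dropout,
         heads = heads,
         boundary_dim = as.integer(boundary_dim),
         seed = as.integer(seed)),
    class = "joint_model_config"
  )
}

#' Analytic parameter count for a model configuration
#'
#' Closed-form count of trainable parameter entries (including the frozen
#' zero rows of the padding embeddings), verified in the test suite
#' against the actual total size of an initialized model's parameter
#' arrays.
#'
#' @param config a [joint_model_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(config) {
  D <- config$embedding_dim
  H <- config$recurrent_hidden
  C <- config$conv_channels_per_width
  Dc <- D + config$boundary_dim
  n <- config$vocab_size * D
  if ("seg" %in% config$heads)
    n <- n + 2L * (4L * H * (D + H) + 4L * H) + (2L * H * config$n_tags + config$n_tags)
  if ("cls" %in% config$heads) {
    n <- n + sum(config$conv_kernel_widths * Dc * C + C)
    n <- n + length(config$conv_kernel_widths) * C * config$n_classes + config$n_classes
    if (config$boundary_dim > 0L)
      n <- n + (config$n_tags + 1L) * config$boundary_dim
  }
  as.integer(n)
}

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a joint model
#'
#' Weight matrices use Glorot-style uniform initialization; LSTM biases
#' start at zero except the forget gate (set to 1, the standard stabiliser
#' for early training); embeddings start uniform in (-0.1, 0.1) with the
#' padding row frozen at zero.  Initialization is fully determined by
#' `config$seed`.
#'
#' @param config a [joint_model_config()].
#' @param vocab the `jcs_vocabulary` the model is bound to (stored in the
#'   model and in checkpoints).
#' @return An object of class `jcs_model` with fields `config`, `params`
#'   and `vocab`.
#' @export
init_joint_model <- function(config, vocab) {
  stopifnot(inherits(config, "joint_model_config"))
  if (config$vocab_size != vocab$size)
    stop("config$vocab_size does not match the vocabulary")
  D <- config$embedding_dim
  H <- config$recurrent_hidden
  C <- config$conv_channels_per_width
  Dc <- D + config$boundary_dim
  p <- with_local_seed(config$seed, {
    p <- list()
    p$emb <- matrix(stats::runif(config$vocab_size * D, -0.1, 0.1),
                    config$vocab_size, D)
    p$emb[vocab$pad_index, ] <- 0
    if ("seg" %in% config$heads) {
      for (dir in c("lstm_f", "lstm_b")) {
        p[[paste0(dir, "_Wx")]] <- glorot_uniform(D, 4L * H)
        p[[paste0(dir, "_Wh")]] <- glorot_uniform(H, 4L * H)
        b <- numeric(4L * H)
        b[H + seq_len(H)] <- 1  # forget gate
        p[[paste0(dir, "_b")]] <- b
      }
      p$tag_W <- glorot_uniform(2L * H, config$n_tags)
      p$tag_b <- numeric(config$n_tags)
    }
    if ("cls" %in% config$heads) {
      for (k in config$conv_kernel_widths) {
        p[[sprintf("conv_W_%d", k)]] <- glorot_uniform(k * Dc, C)
        p[[sprintf("conv_b_%d", k)]] <- numeric(C)
      }
      p$cls_W <- glorot_uniform(length(config$conv_kernel_widths) * C,
                                config$n_classes)
      p$cls_b <- numeric(config$n_classes)
      if (config$boundary_dim > 0L) {
        p$boundary_emb <- matrix(
          stats::runif((config$n_tags + 1L) * config$boundary_dim, -0.1, 0.1),
          config$n_tags + 1L, config$boundary_dim)
        p$boundary_emb[1L, ] <- 0  # padding row
      }
    }
    p
  })
  structure(list(config = config, params = p, vocab = vocab),
            class = "jcs_model")
}

# ---------------------------------------------------------------------------
# Forward pass
#
# The hot recurrent loops live in src/lstm.cpp (stacked B*T-row layout:
# row (t-1)*B + b is timestep t of batch row b).  The plain-R versions
# below implement the identical recurrence and serve as the reference
# the compiled kernels are tested against.

# One LSTM direction over a batch.  Xt: list over time of B x D input
# matrices; maskN: numeric B x T mask.  Masked (padding) positions zero
# both the hidden and the cell state, so trailing padding can never leak
# into real positions in either direction.
run_lstm_direction <- function(Xt, maskN, Wx, Wh, b, reverse = FALSE) {
  Tn <- length(Xt)
  B <- nrow(Xt[[1L]])
  H <- nrow(Wh)
  i_idx <- seq_len(H); f_idx <- H + i_idx; g_idx <- 2L * H + i_idx
  o_idx <- 3L * H + i_idx
  Bb <- matrix(b, B, 4L * H, byrow = TRUE)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  Hout <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in ts) {
    h_prev <- h; c_prev <- cc
    pre <- Xt[[t]] %*% Wx + h_prev %*% Wh + Bb
    gi <- sigmoid(pre[, i_idx, drop = FALSE])
    gf <- sigmoid(pre[, f_idx, drop = FALSE])
    gg <- tanh(pre[, g_idx, drop = FALSE])
    go <- sigmoid(pre[, o_idx, drop = FALSE])
    c_new <- gf * c_prev + gi * gg
    th <- tanh(c_new)
    h_new <- go * th
    m <- maskN[, t]
    h <- h_new * m
    cc <- c_new * m
    Hout[[t]] <- h
    cache[[t]] <- list(i = gi, f = gf, g = gg, o = go, th = th,
                       c_prev = c_prev, h_prev = h_prev, m = m)
  }
  list(H = Hout, cache = cache, order = ts)
}

run_lstm_direction_backward <- function(lst, Xt, dH, Wx, Wh) {
  Tn <- length(Xt)
  B <- nrow(Xt[[1L]])
  H <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- vector("list", Tn)
  dh_rec <- matrix(0, B, H)
  dc_rec <- matrix(0, B, H)
  for (t in rev(lst$order)) {
    ca <- lst$cache[[t]]
    dh <- (dH[[t]] + dh_rec) * ca$m
    dc <- dc_rec * ca$m
    do_ <- dh * ca$th
    dcn <- dh * ca$o * (1 - ca$th^2) + dc
    di <- dcn * ca$g
    df <- dcn * ca$c_prev
    dg <- dcn * ca$i
    da <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(Xt[[t]], da)
    dWh <- dWh + crossprod(ca$h_prev, da)
    db <- db + colSums(da)
    dh_rec <- tcrossprod(da, Wh)
    dc_rec <- dcn * ca$f
    dX[[t]] <- tcrossprod(da, Wx)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

# Inverted-dropout mask (already scaled); NULL when inactive.
dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

#' Forward pass of the joint model
#'
#' Runs the shared embedding lookup and whichever heads the model carries
#' over one padded batch.  Tag scores are returned in "flat" layout: an
#' `(B*T) x 3` matrix whose row `(t-1)*B + b` scores character `t` of
#' batch row `b` (the same column-major order as `as.vector(batch$mask)`).
#'
#' Max-pooling in the classification head is masked: windows consisting
#' entirely of padding are excluded (filled with `-Inf`), so pooled
#' features are invariant to appending padding.  A batch row with no
#' valid window for some width (an all-padding row) triggers a warning
#' and falls back to pooling over the padding-only windows.
#'
#' @param model a `jcs_model`.
#' @param batch a batch from [make_batches()].
#' @param train logical; `TRUE` enables dropout (drawing from the current
#'   RNG stream).
#' @return list with `tag_scores` (flat matrix or `NULL`), `class_scores`
#'   (`B x 2` or `NULL`) and a `cache` for [model_backward()].
#' @export
model_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config
  p <- model$params
  idx <- batch$indices
  if (any(idx < 1L | idx > cfg$vocab_size))
    stop("model_forward: character index out of range")
  B <- nrow(idx); Tn <- ncol(idx)
  maskN <- batch$mask * 1
  D <- cfg$embedding_dim
  Xstack <- p$emb[as.vector(idx), , drop = FALSE]
  cache <- list(Xstack = Xstack, B = B, Tn = Tn)
  tag_scores <- NULL
  class_scores <- NULL

  if ("seg" %in% cfg$heads) {
    lf <- lstm_forward_cpp(Xstack, maskN, p$lstm_f_Wx, p$lstm_f_Wh,
                           p$lstm_f_b, FALSE)
    lb <- lstm_forward_cpp(Xstack, maskN, p$lstm_b_Wx, p$lstm_b_Wh,
                           p$lstm_b_b, TRUE)
    Hcat <- cbind(lf$H, lb$H)
    dm_tag <- if (train) dropout_mask(nrow(Hcat), ncol(Hcat), cfg$dropout)
    Hd <- if (is.null(dm_tag)) Hcat else Hcat * dm_tag
    tag_scores <- Hd %*% p$tag_W +
      matrix(p$tag_b, nrow(Hd), cfg$n_tags, byrow = TRUE)
    cache$lf <- lf; cache$lb <- lb; cache$Hd <- Hd; cache$dm_tag <- dm_tag
  }

  if ("cls" %in% cfg$heads) {
    Dc <- D + cfg$boundary_dim
    if (cfg$boundary_dim > 0L) {
      if (is.null(batch$boundary))
        stop("model_forward: model expects boundary tags but batch has none")
      Cstack <- cbind(Xstack,
                      p$boundary_emb[as.vector(batch$boundary) + 1L, ,
                                     drop = FALSE])
    } else Cstack <- Xstack
    # B x (T*Dc) with position-t columns contiguous
    Xbig <- matrix(aperm(array(Cstack, c(B, Tn, Dc)), c(1L, 3L, 2L)),
                   B, Tn * Dc)
    maskc <- batch$mask
    Tc <- Tn
    kmax <- max(cfg$conv_kernel_widths)
    if (Tc < kmax) {  # pad short sentences up to the widest kernel
      Xbig <- cbind(Xbig, matrix(0, B, (kmax - Tc) * Dc))
      maskc <- cbind(maskc, matrix(FALSE, B, kmax - Tc))
      Tc <- kmax
    }
    conv_cache <- list()
    pooled <- NULL
    warned_dead <- FALSE
    for (k in cfg$conv_kernel_widths) {
      W <- p[[sprintf("conv_W_%d", k)]]
      bvec <- p[[sprintf("conv_b_%d", k)]]
      C <- length(bvec)
      P <- Tc - k + 1L
      valid <- vapply(seq_len(P), function(q)
        rowSums(maskc[, q:(q + k - 1L), drop = FALSE]) > 0, logical(B))
      valid <- matrix(valid, nrow = B)  # B x P
      dead <- rowSums(valid) == 0L
      if (any(dead)) {
        if (!warned_dead) {
          warning("all-padding row(s) in batch: pooling over padding-only windows")
          warned_dead <- TRUE
        }
        valid[dead, ] <- TRUE
      }
      M <- matrix(-Inf, B, C)
      Pidx <- matrix(0L, B, C)
      Zs <- vector("list", P)
      bmat <- matrix(bvec, B, C, byrow = TRUE)
      for (q in seq_len(P)) {
        cols <- ((q - 1L) * Dc + 1L):((q + k - 1L) * Dc)
        Z <- Xbig[, cols, drop = FALSE] %*% W + bmat
        Zs[[q]] <- Z
        A <- pmax(Z, 0)
        A[!valid[, q], ] <- -Inf
        upd <- which(A > M)  # which() ignores NaN activations, so a
        M[upd] <- A[upd]     # diverged forward surfaces as a non-finite
        Pidx[upd] <- q       # loss rather than an indexing error
      }
      conv_cache[[as.character(k)]] <- list(Zs = Zs, Pidx = Pidx, P = P)
      pooled <- if (is.null(pooled)) M else cbind(pooled, M)
    }
    dm_cls <- if (train) dropout_mask(B, ncol(pooled), cfg$dropout)
    pooled_d <- if (is.null(dm_cls)) pooled else pooled * dm_cls
    class_scores <- pooled_d %*% p$cls_W +
      matrix(p$cls_b, B, cfg$n_classes, byrow = TRUE)
    cache$conv <- conv_cache
    cache$Xbig <- Xbig
    cache$Tc <- Tc
    cache$Dc <- Dc
    cache$pooled_d <- pooled_d
    cache$dm_cls <- dm_cls
  }

  list(tag_scores = tag_scores, class_scores = class_scores, cache = cache)
}

# Scatter stacked per-position input gradients back onto embedding rows.
# dStack: (B*T) x D gradients; index_vector: B*T row ids in the same order.
accumulate_row_grads <- function(dStack, index_vector, n_rows, frozen_row) {
  rs <- rowsum(dStack, index_vector)
  out <- matrix(0, n_rows, ncol(dStack))
  out[as.integer(rownames(rs)), ] <- rs
  out[frozen_row, ] <- 0
  out
}

#' Backward pass of the joint model
#'
#' Given upstream gradients on the tag scores and/or class scores,
#' returns parameter gradients *separately per task*: `$seg` holds the
#' gradients of the segmentation objective (embedding, both LSTM
#' directions, tag projection) and `$cls` those of the classification
#' objective (embedding, convolutions, class projection, boundary
#' embedding).  Keeping the tasks separate lets the training loop combine
#' them under any loss-weighting strategy and gives gradient
#' normalization the per-task gradient norms on the shared embedding.
#'
#' @param model a `jcs_model`.
#' @param batch the batch passed to [model_forward()].
#' @param fwd the result of [model_forward()].
#' @param d_tag_scores gradient w.r.t. `fwd$tag_scores` (flat layout), or
#'   `NULL`.
#' @param d_class_scores gradient w.r.t. `fwd$class_scores`, or `NULL`.
#' @return list with elements `seg` and `cls`, each a named list of
#'   gradient arrays matching `model$params` names.
#' @export
model_backward <- function(model, batch, fwd, d_tag_scores = NULL,
                           d_class_scores = NULL) {
  cfg <- model$config
  p <- model$params
  ca <- fwd$cache
  B <- ca$B; Tn <- ca$Tn
  D <- cfg$embedding_dim
  out <- list(seg = NULL, cls = NULL)

  if (!is.null(d_tag_scores)) {
    g <- list()
    g$tag_W <- crossprod(ca$Hd, d_tag_scores)
    g$tag_b <- colSums(d_tag_scores)
    dHd <- tcrossprod(d_tag_scores, p$tag_W)
    if (!is.null(ca$dm_tag)) dHd <- dHd * ca$dm_tag
    H <- cfg$recurrent_hidden
    maskN <- batch$mask * 1
    bf <- lstm_backward_cpp(ca$Xstack, maskN, p$lstm_f_Wx, p$lstm_f_Wh,
                            ca$lf$H, ca$lf$gates, ca$lf$cnew,
                            dHd[, seq_len(H), drop = FALSE], FALSE)
    bb <- lstm_backward_cpp(ca$Xstack, maskN, p$lstm_b_Wx, p$lstm_b_Wh,
                            ca$lb$H, ca$lb$gates, ca$lb$cnew,
                            dHd[, H + seq_len(H), drop = FALSE], TRUE)
    g$lstm_f_Wx <- bf$Wx; g$lstm_f_Wh <- bf$Wh; g$lstm_f_b <- as.numeric(bf$b)
    g$lstm_b_Wx <- bb$Wx; g$lstm_b_Wh <- bb$Wh; g$lstm_b_b <- as.numeric(bb$b)
    g$emb <- accumulate_row_grads(bf$dX + bb$dX, as.vector(batch$indices),
                                  cfg$vocab_size, model$vocab$pad_index)
    out$seg <- g
  }

  if (!is.null(d_class_scores)) {
    g <- list()
    g$cls_W <- crossprod(ca$pooled_d, d_class_scores)
    g$cls_b <- colSums(d_class_scores)
    dPooled <- tcrossprod(d_class_scores, p$cls_W)
    if (!is.null(ca$dm_cls)) dPooled <- dPooled * ca$dm_cls
    Dc <- ca$Dc
    dXbig <- matrix(0, B, ca$Tc * Dc)
    C <- cfg$conv_channels_per_width
    off <- 0L
    for (k in cfg$conv_kernel_widths) {
      cc <- ca$conv[[as.character(k)]]
      W <- p[[sprintf("conv_W_%d", k)]]
      dM <- dPooled[, off + seq_len(C), drop = FALSE]
      dW <- matrix(0, nrow(W), ncol(W))
      dbv <- numeric(C)
      for (q in seq_len(cc$P)) {
        sel <- cc$Pidx == q
        if (!any(sel)) next
        dZ <- dM * sel
        dZ[cc$Zs[[q]] <= 0] <- 0
        cols <- ((q - 1L) * Dc + 1L):((q + k - 1L) * Dc)
        dW <- dW + crossprod(ca$Xbig[, cols, drop = FALSE], dZ)
        dbv <- dbv + colSums(dZ)
        dXbig[, cols] <- dXbig[, cols] + tcrossprod(dZ, W)
      }
      g[[sprintf("conv_W_%d", k)]] <- dW
      g[[sprintf("conv_b_%d", k)]] <- dbv
      off <- off + C
    }
    # back to stacked layout; rows beyond B*Tn belong to the columns
    # added for sentences shorter than the widest kernel and are dropped
    dCstack <- matrix(aperm(array(dXbig, c(B, Dc, ca$Tc)), c(1L, 3L, 2L)),
                      B * ca$Tc, Dc)[seq_len(B * Tn), , drop = FALSE]
    g$emb <- accumulate_row_grads(dCstack[, seq_len(D), drop = FALSE],
                                  as.vector(batch$indices),
                                  cfg$vocab_size, model$vocab$pad_index)
    if (cfg$boundary_dim > 0L) {
      g$boundary_emb <- accumulate_row_grads(
        dCstack[, D + seq_len(cfg$boundary_dim), drop = FALSE],
        as.vector(batch$boundary) + 1L, cfg$n_tags + 1L, 1L)
    }
    out$cls <- g
  }
  out
}

# ---------------------------------------------------------------------------
# Prediction

#' Predict segmentation and class for new sentences
#'
#' Runs the model in evaluation mode (no dropout): per-character tag
#' argmax decoded to words via [decode_bio()], and class probabilities by
#' softmax over the classification scores.
#'
#' @param object a trained `jcs_model`.
#' @param newdata a list of `annotated_record`s, or a character vector of
#'   raw (unsegmented) sentences.
#' @param batch_size batch size used for inference.
#' @param ... unused.
#' @return list with one element per sentence: `words` (character vector,
#'   `NULL` if the model has no segmentation head), `label` (predicted
#'   class), `prob` (probability of the predicted class) and `score`
#'   (probability of class 1, usable as an ROC score).
#' @export
predict.jcs_model <- function(object, newdata, batch_size = 64L, ...) {
  if (is.character(newdata)) {
    if (any(!nzchar(newdata))) stop("empty input sentence")
    newdata <- lapply(newdata, function(s)
      annotated_record(strsplit(s, "")[[1L]], label = 0L))
  }
  if (length(newdata) == 0L) return(list())
  cfg <- object$config
  batches <- make_batches(newdata, object$vocab, batch_size = batch_size,
                          shuffle_seed = NULL)
  out <- vector("list", length(newdata))
  for (bt in batches) {
    fwd <- model_forward(object, bt, train = FALSE)
    B <- nrow(bt$indices); Tn <- ncol(bt$indices)
    probs <- if (!is.null(fwd$class_scores)) softmax_rows(fwd$class_scores)
    for (b in seq_len(B)) {
      id <- bt$record_ids[[b]]
      res <- list(words = NULL, label = NA_integer_, prob = NA_real_,
                  score = NA_real_)
      if (!is.null(fwd$tag_scores)) {
        L <- sum(bt$mask[b, ])
        rows <- (seq_len(L) - 1L) * B + b
        tag_ids <- max.col(fwd$tag_scores[rows, , drop = FALSE],
                           ties.method = "first")
        tags <- c("B", "I", "O")[tag_ids]
        res$words <- decode_bio(tags, newdata[[id]]$chars)
        res$tags <- tags
      }
      if (!is.null(probs)) {
        res$label <- which.max(probs[b, ]) - 1L
        res$prob <- max(probs[b, ])
        res$score <- probs[b, 2L]
      }
      out[[id]] <- res
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Checkpoints

#' Save a model checkpoint
#'
#' A checkpoint is a single serialized file holding the format version,
#' the model configuration, all parameter arrays, the vocabulary and its
#' fingerprint.
#'
#' @param model a `jcs_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "jointcws-checkpoint-1",
               config = model$config,
               params = model$params,
               vocab = model$vocab,
               vocab_hash = vocab_fingerprint(model$vocab)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `jcs_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "jointcws-checkpoint-1"))
    stop("not a jointcws checkpoint: ", path)
  if (!identical(x$vocab_hash, vocab_fingerprint(x$vocab)))
    stop("checkpoint vocabulary fingerprint mismatch: ", path)
  structure(list(config = x$config, params = x$params, vocab = x$vocab),
            class = "jcs_model")
}
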