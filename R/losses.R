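#' Masked cross-entropy loss for the tagging task
#'
#' Mean, over real-character positions only, of the negative
#' log-softmax probability of the gold tag.  Padding positions contribute
#' exactly zero: appending padding to every row leaves the loss
#' bit-identical.
#'
#' @param tag_scores flat `(B*T) x 3` score matrix from
#'   [model_forward()].
#' @param tag_targets integer `B x T` matrix of gold tags (1 = B, 2 = I,
#'   3 = O; 0 at padding).
#' @param mask logical `B x T` matrix, `TRUE` at real characters.
#' @param with_grad if `TRUE`, also return the gradient w.r.t.
#'   `tag_scores`.
#' @return the scalar loss, or (with `with_grad`) a list
#'   `list(loss, grad)`.
#' @export
masked_tag_loss <- function(tag_scores, tag_targets, mask, with_grad = FALSE) {
  sel <- which(as.vector(mask))
  if (length(sel) == 0L) stop("masked_tag_loss: mask selects no positions")
  targets <- as.vector(tag_targets)[sel]
  sc <- tag_scores[sel, , drop = FALSE]
  ls <- log_softmax_rows(sc)
  n <- length(sel)
  loss <- -mean(ls[cbind(seq_len(n), targets)])
  if (!with_grad) return(loss)
  gsel <- exp(ls)
  gsel[cbind(seq_len(n), targets)] <- gsel[cbind(seq_len(n), targets)] - 1
  grad <- matrix(0, nrow(tag_scores), ncol(tag_scores))
  grad[sel, ] <- gsel / n
  list(loss = loss, grad = grad)
}

#' Cross-entropy loss for the classification task
#'
#' Mean negative log-softmax probability of the true class.
#'
#' @param class_scores `B x 2` score matrix.
#' @param labels integer vector of labels in `{0, 1}`.
#' @param with_grad if `TRUE`, also return the gradient w.r.t.
#'   `class_scores`.
#' @return the scalar loss, or (with `with_grad`) `list(loss, grad)`.
#' @export
class_loss <- function(class_scores, labels, with_grad = FALSE) {
  if (!all(labels %in% c(0L, 1L))) stop("class_loss: labels must be 0 or 1")
  B <- nrow(class_scores)
  ls <- log_softmax_rows(class_scores)
  cols <- labels + 1L
  loss <- -mean(ls[cbind(seq_len(B), cols)])
  if (!with_grad) return(loss)
  grad <- exp(ls)
  grad[cbind(seq_len(B), cols)] <- grad[cbind(seq_len(B), cols)] - 1
  list(loss = loss, grad = grad / B)
}

#' Loss-weighting state for the joint objective
#'
#' The joint objective is `Loss = r0 * L0 + r1 * L1`, with `L0` the
#' masked tagging loss and `L1` the classification loss.  Four strategies
#' set the weights:
#'
#' * `fixed`: constant weights (the grid-search setting; the default is
#'   `r0 = r1 = 0.4`, the optimum of the default grid under validation
#'   accuracy).
#' * `gradnorm`: gradient normalization — weights are stepped so each
#'   task's gradient norm on the shared embedding tracks a target set by
#'   its relative training rate, then renormalized to sum to 2.
#' * `dwa`: dynamic weight averaging — softmax (temperature `T`) of the
#'   ratio of the last two epochs' losses, scaled to sum to 2.
#' * `uncertainty`: learned homoscedastic task noise — per-task
#'   log-sigmas `s_i` trained with the network; the effective weight of
#'   task i is `exp(-2 s_i)` and each task adds the regularizer `s_i`.
#'
#' @param strategy one of `"fixed"`, `"gradnorm"`, `"dwa"`,
#'   `"uncertainty"`.
#' @param r0,r1 initial (or fixed) weights for segmentation and
#'   classification.
#' @param alpha gradnorm asymmetry exponent.
#' @param temperature dwa softmax temperature.
#' @param gradnorm_lr step size of the gradnorm weight update.
#' @return an object of class `weight_state`.
#' @export
weight_state <- function(strategy = c("fixed", "gradnorm", "dwa", "uncertainty"),
                         r0 = 1, r1 = 1, alpha = 1.5, temperature = 2,
                         gradnorm_lr = 0.025) {
  strategy <- match.arg(strategy)
  if (r0 < 0 || r1 < 0) stop("weights must be non-negative")
  structure(
    list(strategy = strategy, r0 = r0, r1 = r1,
         alpha = alpha, temperature = temperature,
         gradnorm_lr = gradnorm_lr,
         initial_losses = NULL,        # gradnorm
         gradnorm_m = c(0, 0), gradnorm_v = c(0, 0), gradnorm_t = 0L,
         loss_history = list(),        # dwa: per-epoch c(L0, L1)
         log_sigma = c(0, 0)),         # uncertainty
    class = "weight_state"
  )
}

#' Effective task weights of a weighting state
#'
#' @param state a [weight_state()].
#' @return numeric `c(r0, r1)`; for the uncertainty strategy these are
#'   `exp(-2 * log_sigma)`.
#' @export
effective_weights <- function(state) {
  if (state$strategy == "uncertainty") exp(-2 * state$log_sigma)
  else c(state$r0, state$r1)
}

#' Combine task losses into the joint loss
#'
#' For fixed/gradnorm/dwa strategies returns `r0*L0 + r1*L1`; for the
#' uncertainty strategy returns
#' `exp(-2 s0) L0 + s0 + exp(-2 s1) L1 + s1`.
#'
#' @param L0 segmentation loss.
#' @param L1 classification loss.
#' @param state a [weight_state()].
#' @return scalar joint loss.
#' @export
joint_loss <- function(L0, L1, state) {
  if (!is.finite(L0) || !is.finite(L1)) stop("joint_loss: non-finite task loss")
  w <- effective_weights(state)
  out <- w[1L] * L0 + w[2L] * L1
  if (state$strategy == "uncertainty") out <- out + sum(state$log_sigma)
  out
}

#' Gradient-normalization weight update
#'
#' Implements the gradient-normalization rule on the shared embedding
#' (the trunk common to both heads): with per-task gradient norms
#' `G_i = r_i * ||grad_emb L_i||`, inverse training rates
#' `Ltilde_i = L_i / L_i(0)` and relative rates
#' `rho_i = Ltilde_i / mean(Ltilde)`, the targets are
#' `mean(G) * rho_i^alpha`, and the weights descend the gradient of
#' `sum_i |G_i - target_i|` (targets treated as constants,
#' `d/dr_i = sign(G_i - target_i) * g_i`) with Adam moments at learning
#' rate `gradnorm_lr`, making the step size invariant to the absolute
#' scale of the task gradients.  Weights are clamped to at least 1e-4 and
#' renormalized to sum to 2.
#'
#' @param state a [weight_state()] with strategy `"gradnorm"`.
#' @param losses numeric `c(L0, L1)` of current (unweighted) task losses.
#' @param grad_norms numeric `c(g0, g1)`: norms of the *unweighted*
#'   per-task gradients on the shared embedding.
#' @return the updated state.
#' @export
update_weights_gradnorm <- function(state, losses, grad_norms) {
  stopifnot(state$strategy == "gradnorm")
  if (is.null(state$initial_losses)) {
    if (any(losses <= 0)) stop("gradnorm: initial task losses must be positive")
    state$initial_losses <- losses
  }
  r <- c(state$r0, state$r1)
  G <- r * grad_norms
  Ltilde <- losses / state$initial_losses
  rho <- Ltilde / mean(Ltilde)
  target <- mean(G) * rho^state$alpha
  grad_r <- sign(G - target) * grad_norms
  state$gradnorm_t <- state$gradnorm_t + 1L
  state$gradnorm_m <- 0.9 * state$gradnorm_m + 0.1 * grad_r
  state$gradnorm_v <- 0.999 * state$gradnorm_v + 0.001 * grad_r^2
  mhat <- state$gradnorm_m / (1 - 0.9^state$gradnorm_t)
  vhat <- state$gradnorm_v / (1 - 0.999^state$gradnorm_t)
  r <- r - state$gradnorm_lr * mhat / (sqrt(vhat) + 1e-8)
  r <- pmax(r, 1e-4)
  r <- 2 * r / sum(r)
  state$r0 <- r[1L]; state$r1 <- r[2L]
  state
}

#' Dynamic-weight-averaging update (per epoch)
#'
#' Appends the epoch's mean task losses to the history, then sets
#' `w_i = L_i(t-1) / L_i(t-2)` and
#' `r_i = 2 exp(w_i / T) / sum_j exp(w_j / T)`.  The first two epochs use
#' uniform weights.
#'
#' @param state a [weight_state()] with strategy `"dwa"`.
#' @param epoch_losses numeric `c(L0, L1)`: this epoch's mean task
#'   losses.
#' @return the updated state.
#' @export
update_weights_dwa <- function(state, epoch_losses) {
  stopifnot(state$strategy == "dwa")
  state$loss_history <- c(state$loss_history, list(epoch_losses))
  n <- length(state$loss_history)
  if (n < 2L) {
    state$r0 <- 1; state$r1 <- 1
    return(state)
  }
  prev1 <- state$loss_history[[n]]
  prev2 <- state$loss_history[[n - 1L]]
  if (any(prev2 == 0)) stop("dwa: zero loss in history")
  w <- prev1 / prev2
  e <- exp(w / state$temperature)
  r <- 2 * e / sum(e)
  state$r0 <- r[1L]; state$r1 <- r[2L]
  state
}

#' Gradient of the uncertainty-weighted joint loss in the log-sigmas
#'
#' With joint loss `exp(-2 s0) L0 + s0 + exp(-2 s1) L1 + s1`, the
#' gradient in `s_i` is `-2 exp(-2 s_i) L_i + 1`; the `+1` regularizer
#' term prevents the weights collapsing to zero.
#'
#' @param state a [weight_state()] with strategy `"uncertainty"`.
#' @param losses numeric `c(L0, L1)`.
#' @return numeric gradient `c(d/ds0, d/ds1)`.
#' @export
uncertainty_log_sigma_grad <- function(state, losses) {
  stopifnot(state$strategy == "uncertainty")
  -2 * exp(-2 * state$log_sigma) * losses + 1
}

#' Plain gradient step on the uncertainty log-sigmas
#'
#' Used when the log-sigmas are not folded into the main optimizer (the
#' training loop gives them Adam slots instead).
#'
#' @param state a [weight_state()] with strategy `"uncertainty"`.
#' @param losses numeric `c(L0, L1)`.
#' @param lr step size.
#' @return the updated state.
#' @export
update_weights_uncertainty <- function(state, losses, lr = 0.001) {
  g <- uncertainty_log_sigma_grad(state, losses)
  state$log_sigma <- state$log_sigma - lr * g
  state
}

#' Exhaustive grid search over fixed loss weights
#'
#' Trains the joint model once per weight pair on a grid and selects the
#' pair with the highest validation classification accuracy.
#'
#' @param splits a train/val/test split from [split_dataset()].
#' @param vocab a `jcs_vocabulary`.
#' @param model_config a [joint_model_config()].
#' @param train_config a [train_config()]; its strategy is overridden to
#'   `"fixed"`.
#' @param grid numeric vector of candidate weights for each task
#'   (default `c(0.1, 0.2, 0.3, 0.4, 0.5)`).
#' @return list with `best` (`c(r0, r1)`), `results` (data frame of grid
#'   points and validation accuracy) and `run` (the best run's result).
#' @export
grid_search_weights <- function(splits, vocab, model_config, train_config,
                                grid = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  results <- expand.grid(r0 = grid, r1 = grid)
  results$val_class_accuracy <- NA_real_
  best <- NULL; best_acc <- -Inf; best_run <- NULL
  for (i in seq_len(nrow(results))) {
    tc <- train_config
    tc$strategy <- "fixed"
    tc$fixed_weights <- c(results$r0[i], results$r1[i])
    run <- train_joint(splits, vocab, model_config, tc)
    acc <- run$best_val_class_accuracy
    results$val_class_accuracy[i] <- acc
    if (acc > best_acc) {
      best_acc <- acc
      best <- c(results$r0[i], results$r1[i])
      best_run <- run
    }
  }
  list(best = best, results = results, run = best_run)
}
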