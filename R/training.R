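# Optimization: He initialization, Adam with l2 weight decay, a
# plateau-driven learning-rate schedule on the exponential moving average
# of the training loss, the stopping rule, and k-fold cross-validation
# splits.

#' He-normal initialization
#'
#' Draws every convolution weight from `Normal(0, sqrt(2/fan_in))`, zeroes
#' all biases, sets instance-norm affines to identity, then re-initializes
#' the attention gates to the pass-through regime
#' ([init_pass_through()]).
#'
#' @param network a `seg_network`.
#' @param seed integer seed (same seed, same parameters).
#' @return The re-initialized network.
#' @export
he_init <- function(network, seed = 1L) {
  network$params <- with_seed(seed, lapply(network$param_info, init_param))
  init_pass_through(network, seed = derive_seed(seed, 777L))
}

#' Training-schedule state
#'
#' Tracks the learning rate and the exponential moving average (EMA) of the
#' training loss for the plateau schedule: whenever the EMA has not
#' improved for `patience` consecutive epochs, the learning rate is
#' multiplied by `factor` and the patience counter resets.
#'
#' @param initial_lr starting learning rate.
#' @param ema_beta EMA coefficient (weight of the previous EMA value).
#' @param patience epochs without improvement before a reduction.
#' @param factor multiplicative learning-rate reduction.
#' @param min_lr training stops once `lr` drops below this.
#' @param max_epochs training stops after this many epochs.
#' @param improve_tol minimal EMA decrease counted as an improvement.
#' @return A `train_state` object.
#' @export
train_state <- function(initial_lr = 3e-5, ema_beta = 0.9, patience = 30,
                        factor = 0.2, min_lr = 1e-6, max_epochs = 1000,
                        improve_tol = 1e-5) {
  structure(list(epoch = 0L, lr = initial_lr, loss_ema = NA_real_,
                 best_ema = Inf, epochs_since_improvement = 0L,
                 ema_beta = ema_beta, patience = as.integer(patience),
                 factor = factor, min_lr = min_lr,
                 max_epochs = as.integer(max_epochs),
                 improve_tol = improve_tol),
            class = "train_state")
}

#' Advance the schedule by one epoch
#'
#' Updates the loss EMA (`ema <- beta*ema + (1-beta)*loss`; the first epoch
#' initializes it to the loss), tracks the best EMA seen, and reduces the
#' learning rate by `factor` when `patience` epochs pass without
#' improvement.
#'
#' @param state a [train_state()].
#' @param epoch_loss mean training loss of the finished epoch.
#' @return The updated state.
#' @export
schedule_step <- function(state, epoch_loss) {
  state$epoch <- state$epoch + 1L
  state$loss_ema <- if (is.na(state$loss_ema)) epoch_loss
    else state$ema_beta * state$loss_ema + (1 - state$ema_beta) * epoch_loss
  if (state$loss_ema < state$best_ema - state$improve_tol) {
    state$best_ema <- state$loss_ema
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
  }
  if (state$epochs_since_improvement >= state$patience) {
    state$lr <- state$lr * state$factor
    state$epochs_since_improvement <- 0L
  }
  state
}

#' Stopping rule
#'
#' @param state a [train_state()].
#' @return `TRUE` once the learning rate has fallen below `min_lr` or the
#'   epoch cap is reached.
#' @export
should_stop <- function(state) {
  state$lr < state$min_lr || state$epoch >= state$max_epochs
}

#' Deterministic k-fold cross-validation splits
#'
#' Shuffles the case ids with the given seed and partitions them into `k`
#' near-equal validation folds; the validation sets are pairwise disjoint
#' and exhaust the id list.
#'
#' @param case_ids character or integer vector of case ids.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return List of `k` folds, each with `fold_id`, `train_ids`, `val_ids`.
#' @export
make_folds <- function(case_ids, k = 5, seed = 1L) {
  n <- length(case_ids)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer cases (", n, ") than folds (", k, ")")
  perm <- with_seed(seed, sample(case_ids))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- perm[starts[i]:ends[i]]
    list(fold_id = i - 1L, train_ids = setdiff(perm, val), val_ids = val)
  })
}

# --- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g) || length(g) == 0L) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Train a segmentation network
#'
#' Runs the full optimization loop: foreground-guaranteed patch batches,
#' optional on-the-fly augmentation, the combined dice + cross-entropy
#' objective backpropagated per sample, Adam with l2 weight decay, and the
#' plateau learning-rate schedule with its stopping rule.  An epoch is one
#' pass worth of iterations over the training cases
#' (`ceiling(n_cases / batch_size)` batches).
#'
#' @param network a `seg_network` (will be trained from its current
#'   parameters).
#' @param cases list of preprocessed cases (normalized `image`, `mask`).
#' @param plan a `seg_plan` providing patch and batch size.
#' @param epochs epoch cap for this call (the schedule may stop earlier).
#' @param lr initial learning rate (published default `3e-5`; scaled-down
#'   phantom runs use a larger rate, see the package vignette).
#' @param weight_decay l2 coefficient added to the gradient.
#' @param augment an [augment_config()] or `NULL` to disable augmentation.
#' @param seed master seed for sampling/augmentation/dropout.
#' @param state optionally a [train_state()] to continue from.
#' @param verbose print per-epoch progress.
#' @return List with `network` (parameters of the best loss-EMA epoch),
#'   `final_network`, `log` (per-epoch data.frame), and `state`.
#' @export
train_model <- function(network, cases, plan, epochs = 50,
                        lr = 3e-5, weight_decay = 3e-5,
                        augment = NULL, seed = 1L, state = NULL,
                        verbose = FALSE) {
  if (length(cases) == 0L) stop("no training cases")
  spec <- network$spec
  if (is.null(state)) state <- train_state(initial_lr = lr)
  ast <- adam_state(network$params)
  iters <- ceiling(length(cases) / plan$batch_size)
  log <- vector("list", epochs)
  best_params <- network$params
  best_ema <- Inf
  with_seed(derive_seed(seed, 1L), {
    for (ep in seq_len(epochs)) {
      ep_tot <- ep_dice <- ep_ce <- 0
      for (it in seq_len(iters)) {
        batch <- sample_batch(cases, plan$batch_size, plan$patch_size)
        if (!is.null(augment)) batch <- lapply(batch, augment_patch, config = augment)
        grads <- NULL
        for (pair in batch) {
          g <- net_graph(network, pair$image, train = TRUE)
          lg <- loss_and_grad(ag_value(g$tape, g$logits), pair$labels, spec$num_classes)
          if (!is.finite(lg$total))
            stop("non-finite loss at epoch ", state$epoch + 1L, ", iteration ", it,
                 " (dice ", lg$dice, ", cross-entropy ", lg$cross_entropy, ")")
          ag_backward(g$tape, g$logits, lg$grad_logits)
          pid_names <- ls(g$pids)
          bg <- setNames(lapply(pid_names, function(nm) ag_grad(g$tape, g$pids[[nm]])), pid_names)
          if (is.null(grads)) grads <- bg
          else for (nm in pid_names) {
            if (is.null(bg[[nm]])) next
            grads[[nm]] <- if (is.null(grads[[nm]])) bg[[nm]] else grads[[nm]] + bg[[nm]]
          }
          ep_tot <- ep_tot + lg$total; ep_dice <- ep_dice + lg$dice; ep_ce <- ep_ce + lg$cross_entropy
        }
        grads <- lapply(grads, function(g) if (is.null(g)) NULL else g / plan$batch_size)
        upd <- adam_step(network$params, grads, ast, state$lr, weight_decay)
        network$params <- upd$params
        ast <- upd$state
      }
      nsamp <- iters * plan$batch_size
      state <- schedule_step(state, ep_tot / nsamp)
      log[[ep]] <- data.frame(epoch = state$epoch, loss = ep_tot / nsamp,
                              dice_loss = ep_dice / nsamp, ce_loss = ep_ce / nsamp,
                              ema = state$loss_ema, lr = state$lr)
      if (state$loss_ema < best_ema) {
        best_ema <- state$loss_ema
        best_params <- network$params
      }
      if (verbose)
        message(sprintf("epoch %d: loss %.4f (dice %.4f, ce %.4f), ema %.4f, lr %.2e",
                        state$epoch, ep_tot / nsamp, ep_dice / nsamp, ep_ce / nsamp,
                        state$loss_ema, state$lr))
      if (should_stop(state)) break
    }
  })
  best <- network
  best$params <- best_params
  list(network = best, final_network = network,
       log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
       state = state)
}
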