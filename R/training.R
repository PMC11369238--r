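#' Masked-token cross-entropy loss
#'
#' Mean negative log-probability of the true tokens over the masked
#' positions only; unmasked positions never contribute.
#'
#' @param log_probs L x 33 matrix of per-position log-probabilities.
#' @param token_targets Data.frame with `position` and true `token` columns.
#' @return Non-negative scalar (nats).
#' @export
ce_loss <- function(log_probs, token_targets) {
  if (is.null(token_targets) || nrow(token_targets) == 0L)
    stop("ce_loss requires at least one token target")
  idx <- cbind(token_targets$position, token_targets$token)
  -mean(log_probs[idx])
}

# gradient of ce_loss w.r.t. log_probs
.ce_grad <- function(log_probs, token_targets) {
  d <- matrix(0, nrow(log_probs), ncol(log_probs))
  idx <- cbind(token_targets$position, token_targets$token)
  d[idx] <- d[idx] - 1 / nrow(token_targets)
  d
}

#' Point-completion Chamfer loss
#'
#' Symmetric Chamfer distance between the predicted coordinates at the
#' masked point indices and the true masked coordinates. Computed over
#' masked points only (the completion targets).
#'
#' @param recovered_coords L x 3 matrix of decoded coordinates.
#' @param coord_targets Data.frame with `index`, `x`, `y`, `z`.
#' @return Non-negative scalar (Angstrom squared).
#' @export
cd_loss <- function(recovered_coords, coord_targets) {
  if (is.null(coord_targets) || nrow(coord_targets) == 0L)
    stop("cd_loss requires at least one coordinate target")
  P <- recovered_coords[coord_targets$index, , drop = FALSE]
  T_ <- as.matrix(coord_targets[, c("x", "y", "z")])
  chamfer_distance(P, T_)
}

# gradient of cd_loss w.r.t. recovered_coords (L x 3)
.cd_grad <- function(recovered_coords, coord_targets) {
  idx <- coord_targets$index
  P <- recovered_coords[idx, , drop = FALSE]
  T_ <- as.matrix(coord_targets[, c("x", "y", "z")])
  m <- nrow(P); n <- nrow(T_)
  d2 <- .cross_dist2(P, T_)
  nnPT <- apply(d2, 1, which.min)   # for each pred, nearest truth
  nnTP <- apply(d2, 2, which.min)   # for each truth, nearest pred
  dP <- (P - T_[nnPT, , drop = FALSE]) / m
  for (j in seq_len(n)) {
    i <- nnTP[j]
    dP[i, ] <- dP[i, ] + (P[i, ] - T_[j, ]) / n
  }
  out <- matrix(0, nrow(recovered_coords), 3)
  out[idx, ] <- dP
  out
}

#' Total self-supervised loss
#'
#' `total = ce_weight * ce + cd_weight * cd` with unit default weights.
#'
#' @param output A `model_output` from [forward()].
#' @param example A `training_example`.
#' @param ce_weight,cd_weight Loss weights (defaults 1).
#' @return List of class `loss_breakdown`: `ce`, `cd`, `total`,
#'   `n_token_targets`, `n_coord_targets`.
#' @export
training_loss <- function(output, example, ce_weight = 1, cd_weight = 1) {
  ce <- ce_loss(output$log_probs, example$token_targets)
  cd <- cd_loss(output$recovered_coords, example$coord_targets)
  structure(list(ce = ce, cd = cd,
                 total = ce_weight * ce + cd_weight * cd,
                 n_token_targets = nrow(example$token_targets),
                 n_coord_targets = nrow(example$coord_targets)),
            class = "loss_breakdown")
}

#' Learning-rate schedule
#'
#' Linear warm-up to `base_lr` over `warmup_steps`, then inverse square
#' root decay: `base_lr * sqrt(warmup / step)`. Continuous at the warm-up
#' boundary; zero at step 0.
#'
#' @param step Non-negative integer step.
#' @param sched A [schedule_config()].
#' @return Learning rate.
#' @export
lr_at <- function(step, sched = schedule_config()) {
  stopifnot(step >= 0)
  if (step <= sched$warmup_steps) sched$base_lr * step / sched$warmup_steps
  else sched$base_lr * sqrt(sched$warmup_steps / step)
}

#' Optimizer / schedule configuration
#'
#' Reference-scale values are `base_lr = 1e-4`, 10,000 warm-up steps, Adam
#' betas (0.9, 0.999) and batch size 480; the desk default batch is 8.
#'
#' @param base_lr Peak learning rate.
#' @param warmup_steps Warm-up length in steps (>= 1).
#' @param betas Adam moment decays.
#' @param batch_size Examples per step.
#' @param total_steps Training steps.
#' @param clip_norm Global gradient-norm clip (default 1).
#' @export
schedule_config <- function(base_lr = 1e-4, warmup_steps = 10000,
                            betas = c(0.9, 0.999), batch_size = 8,
                            total_steps = 200, clip_norm = 1.0) {
  stopifnot(warmup_steps >= 1, base_lr > 0, length(betas) == 2)
  structure(list(base_lr = base_lr, warmup_steps = warmup_steps,
                 betas = betas, batch_size = batch_size,
                 total_steps = total_steps, clip_norm = clip_norm),
            class = "schedule_config")
}

# one Adam update; state holds m, v trees and step counter
.adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
  }
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# gradient of the combined loss for one example (forward with cache)
.example_grad <- function(model, ex, ce_weight = 1, cd_weight = 1) {
  out <- forward(model, ex$seq, ex$cloud, want_cache = TRUE)
  ce <- ce_loss(out$log_probs, ex$token_targets)
  cd <- cd_loss(out$recovered_coords, ex$coord_targets)
  dlp <- .ce_grad(out$log_probs, ex$token_targets) * ce_weight
  dco <- .cd_grad(out$recovered_coords, ex$coord_targets) * cd_weight
  g <- model_backward(model, out, dlp, dco)
  list(grads = g, ce = ce, cd = cd)
}

#' Train the model on self-supervised examples
#'
#' Minibatch Adam with the warm-up / inverse-sqrt schedule, gradient
#' clipping at global norm `clip_norm`, and a per-step loss log. Aborts
#' with a diagnostic if the loss becomes non-finite. Fully seeded: two runs
#' with equal seeds produce identical loss curves.
#'
#' @param model A `mutpoint_model`.
#' @param examples List of `training_example`s.
#' @param sched A [schedule_config()].
#' @param seed Integer seed for batch sampling.
#' @param ce_weight,cd_weight Loss weights.
#' @param checkpoint Optional path; the final model is saved there.
#' @return List with `model` (trained) and `log` (data.frame step, lr, ce,
#'   cd, total).
#' @export
train_model <- function(model, examples, sched = schedule_config(), seed = 1,
                        ce_weight = 1, cd_weight = 1, checkpoint = NULL) {
  stopifnot(length(examples) >= 1L)
  n <- length(examples)
  state <- NULL
  log <- vector("list", sched$total_steps)
  batch_seeds <- with_seed(child_seed(seed, "batches"),
                           sample.int(2^30, sched$total_steps))
  for (step in seq_len(sched$total_steps)) {
    idx <- with_seed(batch_seeds[step],
                     sample.int(n, min(sched$batch_size, n)))
    acc <- NULL; ce_s <- 0; cd_s <- 0
    for (i in idx) {
      eg <- .example_grad(model, examples[[i]], ce_weight, cd_weight)
      acc <- if (is.null(acc)) eg$grads else tree_add(acc, eg$grads)
      ce_s <- ce_s + eg$ce; cd_s <- cd_s + eg$cd
    }
    nb <- length(idx)
    acc <- tree_scale(acc, 1 / nb)
    ce_m <- ce_s / nb; cd_m <- cd_s / nb
    total <- ce_weight * ce_m + cd_weight * cd_m
    if (!is.finite(total))
      stop("training diverged at step ", step, " (loss = ", total, ")")
    gn <- tree_global_norm(acc)
    if (gn > sched$clip_norm) acc <- tree_scale(acc, sched$clip_norm / gn)
    lr <- lr_at(step, sched)
    up <- .adam_step(model$params, acc, state, lr, sched$betas)
    model$params <- up$params
    state <- up$state
    log[[step]] <- data.frame(step = step, lr = lr, ce = ce_m, cd = cd_m,
                              total = total)
  }
  log <- do.call(rbind, log)
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model, log = log)
}

#' Fine-tune the masked objective on homolog examples
#'
#' Same objective as [train_model()] but a constant learning rate and a
#' fixed number of passes over the examples (the homolog fine-tuning
#' protocol: 3 epochs at learning rate 1e-4). Zero epochs return the model
#' unchanged.
#'
#' @param model A `mutpoint_model`.
#' @param examples List of `training_example`s built from homolog
#'   sequence/structure pairs.
#' @param epochs Number of epochs (default 3).
#' @param lr Constant learning rate (default 1e-4).
#' @param batch_size Minibatch size.
#' @param seed Integer seed for shuffling.
#' @return List with `model` and `log` (per-step losses with an `epoch`
#'   column).
#' @export
finetune_masked_lm <- function(model, examples, epochs = 3, lr = 1e-4,
                               batch_size = 8, seed = 1) {
  stopifnot(epochs >= 0)
  if (epochs == 0) return(list(model = model, log = NULL))
  n <- length(examples)
  state <- NULL
  logs <- list()
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(child_seed(seed, paste0("epoch", ep)), sample.int(n))
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      acc <- NULL; ce_s <- 0; cd_s <- 0
      for (i in idx) {
        eg <- .example_grad(model, examples[[i]])
        acc <- if (is.null(acc)) eg$grads else tree_add(acc, eg$grads)
        ce_s <- ce_s + eg$ce; cd_s <- cd_s + eg$cd
      }
      acc <- tree_scale(acc, 1 / length(idx))
      total <- ce_s / length(idx) + cd_s / length(idx)
      if (!is.finite(total)) stop("fine-tuning diverged (loss = ", total, ")")
      gn <- tree_global_norm(acc)
      if (gn > 1) acc <- tree_scale(acc, 1 / gn)
      up <- .adam_step(model$params, acc, state, lr, c(0.9, 0.999))
      model$params <- up$params
      state <- up$state
      step <- step + 1L
      logs[[step]] <- data.frame(epoch = ep, step = step,
                                 ce = ce_s / length(idx),
                                 cd = cd_s / length(idx), total = total)
    }
  }
  list(model = model, log = do.call(rbind, logs))
}

#' Masked-token accuracy on held-out examples
#'
#' Fraction of masked positions whose argmax token equals the true token.
#'
#' @param model A `mutpoint_model`.
#' @param examples List of `training_example`s.
#' @return Accuracy in `[0, 1]`.
#' @export
masked_token_accuracy <- function(model, examples) {
  hits <- 0L; total <- 0L
  for (ex in examples) {
    out <- forward(model, ex$seq, ex$cloud)
    pred <- max.col(out$log_probs[ex$token_targets$position, , drop = FALSE],
                    ties.method = "first")
    hits <- hits + sum(pred == ex$token_targets$token)
    total <- total + nrow(ex$token_targets)
  }
  hits / total
}
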