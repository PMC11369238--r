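#' Model configuration
#'
#' Desk-scale defaults are the test configuration (`K = 64`, 2 encoder
#' layers, context 128); the full-scale configuration of the reference
#' architecture (`K = 1280`, 33 layers, 20 heads, context 1024) is
#' constructible but never required. `K` must be divisible by both head
#' counts.
#'
#' @param K Embedding width (d_model).
#' @param encoder_layers,encoder_heads Transformer encoder depth and heads.
#' @param context Maximum sequence/cloud length.
#' @param struct_layers,struct_heads Structure-branch transformer depth and
#'   heads.
#' @param knn Neighbourhood size of the structure context (default 30).
#' @param fusion `"sum"` (element-wise sum of sequence and structure
#'   embeddings at aligned positions) or `"concat-project"`.
#' @param ffn_mult Feed-forward width multiplier (default 4).
#' @param vocab Token vocabulary size; fixed at 33.
#' @return Named list of class `model_config`.
#' @export
model_config <- function(K = 64, encoder_layers = 2, encoder_heads = 4,
                         context = 128, struct_layers = 1, struct_heads = 8,
                         knn = 30, fusion = c("sum", "concat-project"),
                         ffn_mult = 4, vocab = 33) {
  fusion <- match.arg(fusion)
  stopifnot(K >= 1, encoder_layers >= 1, encoder_heads >= 1, context >= 1,
            struct_layers >= 0, struct_heads >= 1, knn >= 1, vocab == 33)
  if (K %% encoder_heads != 0) stop("K must be divisible by encoder_heads")
  if (struct_layers > 0 && K %% struct_heads != 0)
    stop("K must be divisible by struct_heads")
  structure(list(K = K, encoder_layers = encoder_layers,
                 encoder_heads = encoder_heads, context = context,
                 struct_layers = struct_layers, struct_heads = struct_heads,
                 knn = knn, fusion = fusion, ffn_mult = ffn_mult,
                 vocab = vocab),
            class = "model_config")
}

#' Initialize a multimodal masked protein model
#'
#' All weights are drawn from a zero-centred normal with standard deviation
#' 0.02; layer norms start at identity. At this initialization per-position
#' token distributions are near-uniform.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return Object of class `mutpoint_model` (fields `config`, `params`,
#'   `hash`).
#' @export
init_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  K <- config$K
  ffK <- K * config$ffn_mult
  Fdim <- 2L * config$knn
  with_seed(seed, {
    p <- list(
      tok_emb = .init_mat(config$vocab, K),
      pos_emb = .init_mat(config$context, K),
      struct = list(
        proj = list(W = .init_mat(Fdim, K), b = rep(0, K)),
        null = stats::rnorm(K, sd = 0.02),
        blocks = if (config$struct_layers > 0)
          lapply(seq_len(config$struct_layers),
                 function(i) .init_block(K, ffK)) else list()),
      enc = lapply(seq_len(config$encoder_layers),
                   function(i) .init_block(K, ffK)),
      ln_f = list(g = rep(1, K), b = rep(0, K)),
      seq_dec = list(W1 = .init_mat(K, K), b1 = rep(0, K),
                     ln = list(g = rep(1, K), b = rep(0, K)),
                     W2 = .init_mat(K, config$vocab),
                     b2 = rep(0, config$vocab)),
      str_dec = list(W1 = .init_mat(K, K), b1 = rep(0, K),
                     W2 = .init_mat(K, K), b2 = rep(0, K),
                     W3 = .init_mat(K, 3), b3 = rep(0, 3)))
    if (config$fusion == "concat-project")
      p$fuse <- list(W = .init_mat(2 * K, K), b = rep(0, K))
    structure(list(config = config, params = p,
                   hash = config_hash(unclass(config))),
              class = "mutpoint_model")
  })
}

#' @export
print.mutpoint_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<mutpoint_model> K=%d, %d encoder layers x %d heads, ",
                     "context %d, %s fusion, %s parameters [%s]\n"),
              cfg$K, cfg$encoder_layers, cfg$encoder_heads, cfg$context,
              cfg$fusion, format(count_parameters(cfg), big.mark = ","),
              x$hash))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count over all weight tensors. The learned absolute-position table
#' is excluded by default so the count does not grow with the configured
#' context length; set `include_positional = TRUE` to include it.
#'
#' @param config A [model_config()].
#' @param include_positional Include the position-embedding table.
#' @return Integer count.
#' @export
count_parameters <- function(config, include_positional = FALSE) {
  m <- init_model(config, seed = 0)
  total <- tree_sum(length, m$params)
  if (!include_positional) total <- total - length(m$params$pos_emb)
  as.integer(total)
}

# invariant per-point features: sorted distances to the knn nearest observed
# points, as two channels exp(-d/4) and d/10, zero-padded to knn entries
.struct_features <- function(cloud, knn) {
  L <- length(cloud$P)
  Feat <- matrix(0, L, 2L * knn)
  obs <- which(cloud$coord_mask & !cloud$pad)
  if (length(obs) < 2L) return(list(Feat = Feat, obs = obs))
  X <- cloud$coords[obs, , drop = FALSE]
  d2 <- .cross_dist2(X, X)
  for (ii in seq_along(obs)) {
    d <- sqrt(d2[ii, -ii])
    kk <- min(knn, length(d))
    ds <- sort(d, partial = seq_len(kk))[seq_len(kk)]
    Feat[obs[ii], seq_len(kk)] <- exp(-ds / 4)
    Feat[obs[ii], knn + seq_len(kk)] <- ds / 10
  }
  list(Feat = Feat, obs = obs)
}

#' Forward pass of the multimodal model
#'
#' Runs the sequence embedding, the SE(3)-invariant structure branch, the
#' transformer encoder and both decoders. Deterministic in evaluation mode.
#' Padded positions are excluded from attention normalization; the structure
#' branch sees only observed points, and coordinate-masked or padded points
#' receive a learned null embedding. Decoded coordinates are predicted in a
#' canonical frame of the observed points and mapped back to the input
#' frame, which makes them rigid-transform equivariant while token
#' log-probabilities and representations are invariant.
#'
#' @param model A `mutpoint_model`.
#' @param seq A `tok_seq`.
#' @param cloud A `protein_cloud` aligned with `seq` (same length).
#' @param want_cache Keep intermediate activations for the backward pass.
#' @return Object of class `model_output`: `log_probs` (L x 33, rows are
#'   log-probabilities), `recovered_coords` (L x 3), `attentions` (list of
#'   layers, each a list of L x L row-stochastic matrices), `residue_reps`
#'   (L x K), `pooled_rep` (K).
#' @export
forward <- function(model, seq, cloud, want_cache = FALSE) {
  stopifnot(inherits(model, "mutpoint_model"), inherits(seq, "tok_seq"),
            inherits(cloud, "protein_cloud"))
  cfg <- model$config
  p <- model$params
  L <- length(seq$tokens)
  if (L != length(cloud$P)) stop("sequence and cloud lengths differ")
  if (L > cfg$context)
    stop("input length ", L, " exceeds model context ", cfg$context)

  seq_emb <- p$tok_emb[seq$tokens, , drop = FALSE] +
    p$pos_emb[seq_len(L), , drop = FALSE]

  sf <- .struct_features(cloud, cfg$knn)
  obs <- sf$obs
  s0 <- matrix(p$struct$null, L, cfg$K, byrow = TRUE)
  if (length(obs) >= 2L) {
    s0[obs, ] <- sweep(sf$Feat[obs, , drop = FALSE] %*% p$struct$proj$W,
                       2, p$struct$proj$b, `+`)
  }
  obs_keep <- logical(L); obs_keep[obs] <- TRUE
  s_caches <- list()
  s <- s0
  if (length(obs) >= 1L && cfg$struct_layers > 0) {
    for (l in seq_len(cfg$struct_layers)) {
      bf <- block_fwd(s, p$struct$blocks[[l]], cfg$struct_heads, obs_keep)
      s <- bf$x
      s_caches[[l]] <- bf$cache
    }
  }

  if (cfg$fusion == "sum") {
    x <- seq_emb + s
    fuse_cache <- NULL
  } else {
    xin <- cbind(seq_emb, s)
    x <- sweep(xin %*% p$fuse$W, 2, p$fuse$b, `+`)
    fuse_cache <- xin
  }

  key_keep <- !seq$pad
  attns <- vector("list", cfg$encoder_layers)
  e_caches <- vector("list", cfg$encoder_layers)
  for (l in seq_len(cfg$encoder_layers)) {
    bf <- block_fwd(x, p$enc[[l]], cfg$encoder_heads, key_keep)
    x <- bf$x
    attns[[l]] <- bf$A
    e_caches[[l]] <- bf$cache
  }
  lnf <- ln_fwd(x, p$ln_f$g, p$ln_f$b)
  reps <- lnf$y

  # sequence decoder: linear -> GELU -> LN -> linear -> log-softmax
  u1 <- sweep(reps %*% p$seq_dec$W1, 2, p$seq_dec$b1, `+`)
  a1 <- gelu_fwd(u1)
  dln <- ln_fwd(a1, p$seq_dec$ln$g, p$seq_dec$ln$b)
  logits <- sweep(dln$y %*% p$seq_dec$W2, 2, p$seq_dec$b2, `+`)
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  log_probs <- logits - lse

  # structure decoder: 3-layer ReLU MLP in the canonical frame
  u2 <- sweep(reps %*% p$str_dec$W1, 2, p$str_dec$b1, `+`)
  r1 <- relu_fwd(u2)
  u3 <- sweep(r1 %*% p$str_dec$W2, 2, p$str_dec$b2, `+`)
  r2 <- relu_fwd(u3)
  y <- sweep(r2 %*% p$str_dec$W3, 2, p$str_dec$b3, `+`)
  frame <- if (length(obs) > 0L)
    canonical_frame(cloud$coords[obs, , drop = FALSE])
  else list(Q = diag(3), c = c(0, 0, 0))
  coords_out <- sweep(y %*% t(frame$Q), 2, frame$c, `+`)

  nonpad <- which(!seq$pad)
  pooled <- if (length(nonpad) > 0)
    colMeans(reps[nonpad, , drop = FALSE]) else colMeans(reps)

  out <- structure(list(log_probs = log_probs,
                        recovered_coords = coords_out,
                        attentions = attns,
                        residue_reps = reps, pooled_rep = pooled,
                        pad = seq$pad),
                   class = "model_output")
  if (want_cache) {
    out$cache <- list(seq = seq, cloud = cloud, sf = sf, obs = obs,
                      obs_keep = obs_keep, s0 = s0, s_caches = s_caches,
                      fuse_cache = fuse_cache, e_caches = e_caches,
                      lnf = lnf$cache, reps = reps,
                      u1 = u1, a1 = a1, dln = dln$cache, hn = dln$y,
                      log_probs = log_probs,
                      u2 = u2, r1 = r1, u3 = u3, r2 = r2, frame = frame)
  }
  out
}

# backward pass: d_log_probs is the gradient of the loss w.r.t. log_probs,
# d_coords w.r.t. recovered_coords (either may be NULL). Returns a gradient
# tree shaped like model$params.
model_backward <- function(model, out, d_log_probs = NULL, d_coords = NULL) {
  cfg <- model$config
  p <- model$params
  cc <- out$cache
  if (is.null(cc)) stop("forward() must be called with want_cache = TRUE")
  L <- nrow(out$log_probs)
  K <- cfg$K
  g <- tree_zeros(p)

  d_reps <- matrix(0, L, K)

  if (!is.null(d_log_probs)) {
    probs <- exp(cc$log_probs)
    dlogits <- d_log_probs - probs * rowSums(d_log_probs)
    g$seq_dec$W2 <- crossprod(cc$hn, dlogits)
    g$seq_dec$b2 <- colSums(dlogits)
    dhn <- dlogits %*% t(p$seq_dec$W2)
    lb <- ln_bwd(dhn, cc$dln)
    g$seq_dec$ln$g <- lb$dg; g$seq_dec$ln$b <- lb$db
    du1 <- gelu_bwd(lb$dx, cc$u1)
    g$seq_dec$W1 <- crossprod(cc$reps, du1)
    g$seq_dec$b1 <- colSums(du1)
    d_reps <- d_reps + du1 %*% t(p$seq_dec$W1)
  }

  if (!is.null(d_coords)) {
    dy <- d_coords %*% cc$frame$Q
    g$str_dec$W3 <- crossprod(cc$r2, dy)
    g$str_dec$b3 <- colSums(dy)
    dr2 <- dy %*% t(p$str_dec$W3)
    du3 <- relu_bwd(dr2, cc$u3)
    g$str_dec$W2 <- crossprod(cc$r1, du3)
    g$str_dec$b2 <- colSums(du3)
    dr1 <- du3 %*% t(p$str_dec$W2)
    du2 <- relu_bwd(dr1, cc$u2)
    g$str_dec$W1 <- crossprod(cc$reps, du2)
    g$str_dec$b1 <- colSums(du2)
    d_reps <- d_reps + du2 %*% t(p$str_dec$W1)
  }

  lfb <- ln_bwd(d_reps, cc$lnf)
  g$ln_f$g <- lfb$dg; g$ln_f$b <- lfb$db
  dx <- lfb$dx
  for (l in rev(seq_len(cfg$encoder_layers))) {
    bb <- block_bwd(dx, p$enc[[l]], cc$e_caches[[l]])
    g$enc[[l]] <- bb$g
    dx <- bb$dx
  }

  if (cfg$fusion == "sum") {
    d_seq_emb <- dx
    ds <- dx
  } else {
    g$fuse$W <- crossprod(cc$fuse_cache, dx)
    g$fuse$b <- colSums(dx)
    dxin <- dx %*% t(p$fuse$W)
    d_seq_emb <- dxin[, seq_len(K), drop = FALSE]
    ds <- dxin[, K + seq_len(K), drop = FALSE]
  }

  # sequence embedding grads
  toks <- cc$seq$tokens
  g$tok_emb <- g$tok_emb +
    rowsum_into(d_seq_emb, toks, cfg$vocab)
  g$pos_emb[seq_len(L), ] <- g$pos_emb[seq_len(L), , drop = FALSE] + d_seq_emb

  # structure branch grads
  obs <- cc$obs
  if (length(obs) >= 1L && cfg$struct_layers > 0) {
    for (l in rev(seq_len(cfg$struct_layers))) {
      bb <- block_bwd(ds, p$struct$blocks[[l]], cc$s_caches[[l]])
      g$struct$blocks[[l]] <- bb$g
      ds <- bb$dx
    }
  }
  if (length(obs) >= 2L) {
    g$struct$proj$W <- crossprod(cc$sf$Feat[obs, , drop = FALSE],
                                 ds[obs, , drop = FALSE])
    g$struct$proj$b <- colSums(ds[obs, , drop = FALSE])
    null_rows <- setdiff(seq_len(L), obs)
  } else null_rows <- seq_len(L)
  if (length(null_rows) > 0)
    g$struct$null <- g$struct$null +
      colSums(ds[null_rows, , drop = FALSE])
  g
}

# scatter-add rows of M into `nbin` bins given by idx
rowsum_into <- function(M, idx, nbin) {
  rs <- rowsum(M, group = idx)
  out <- matrix(0, nbin, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Rigid-transform invariance of token log-probabilities
#'
#' Applies `t` to the cloud and returns the maximum absolute deviation of
#' the token log-probabilities between the transformed and original inputs.
#' The architecture contract is a deviation of at most 1e-4 for any proper
#' rigid transform.
#'
#' @param model A `mutpoint_model`.
#' @param seq,cloud Aligned inputs.
#' @param t A `rigid_transform`.
#' @return Scalar maximum absolute log-probability deviation.
#' @export
invariance_check <- function(model, seq, cloud, t) {
  o1 <- forward(model, seq, cloud)
  o2 <- forward(model, seq, apply_transform(cloud, t))
  real <- !seq$pad
  max(abs(o1$log_probs[real, , drop = FALSE] -
          o2$log_probs[real, , drop = FALSE]))
}

#' Rigid-transform equivariance of recovered coordinates
#'
#' Returns the maximum absolute deviation (Angstrom) between
#' `recovered_coords(R x + t)` and `R recovered_coords(x) + t` over real
#' positions. Contract: at most 1e-3 Angstrom.
#'
#' @inheritParams invariance_check
#' @export
equivariance_check <- function(model, seq, cloud, t) {
  o1 <- forward(model, seq, cloud)
  o2 <- forward(model, seq, apply_transform(cloud, t))
  mapped <- sweep(o1$recovered_coords %*% t(t$rotation), 2, t$translation, `+`)
  real <- !seq$pad
  max(abs(o2$recovered_coords[real, , drop = FALSE] -
          mapped[real, , drop = FALSE]))
}

#' Residue-level and pooled representations
#'
#' @param model A `mutpoint_model`.
#' @param seq,cloud Aligned inputs.
#' @return List with `residue_reps` (L x K) and `pooled_rep` (length K, the
#'   mean of residue representations over non-pad positions).
#' @export
extract_representations <- function(model, seq, cloud) {
  o <- forward(model, seq, cloud)
  list(residue_reps = o$residue_reps, pooled_rep = o$pooled_rep)
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the configuration hash; loading refuses a checkpoint
#' whose stored shapes disagree with its own config.
#'
#' @param model A `mutpoint_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mutpoint_model"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               hash = model$hash), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config)
  if (config_hash(unclass(cfg)) != ck$hash)
    stop("checkpoint hash mismatch: file is inconsistent with its config")
  if (nrow(ck$params$tok_emb) != cfg$vocab ||
      ncol(ck$params$tok_emb) != cfg$K)
    stop("checkpoint parameter shapes do not match config")
  structure(list(config = cfg, params = ck$params, hash = ck$hash),
            class = "mutpoint_model")
}
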