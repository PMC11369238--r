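test_that("forward output satisfies the softmax and attention contracts", {
  m <- small_model()
  inp <- helix_inputs(40, sigma = 0.3, seed = 5)
  o <- forward(m, inp$seq, inp$cloud)
  expect_lt(max(abs(rowSums(exp(o$log_probs)) - 1)), 1e-5)
  for (layer in o$attentions)
    for (A in layer)
      expect_lt(max(abs(rowSums(A) - 1)), 1e-5)
  # determinism
  o2 <- forward(m, inp$seq, inp$cloud)
  expect_identical(o$log_probs, o2$log_probs)
  expect_error(forward(m, inp$seq,
                       protein_cloud(matrix(0, 5, 3), rep("A", 5))),
               "lengths differ")
})

test_that("padded keys are excluded from attention normalization", {
  m <- small_model()
  inp <- helix_inputs(20, sigma = 0.2, seed = 7)
  cp <- crop_or_pad(inp$cloud, inp$seq, context = 40, seed = 1)
  o <- forward(m, cp$seq, cp$cloud)
  pad_cols <- which(cp$seq$pad)
  real_rows <- which(!cp$seq$pad)
  for (layer in o$attentions)
    for (A in layer)
      expect_lt(max(A[real_rows, pad_cols]), 1e-12)
})

test_that("a fresh model is near-uniform at initialization", {
  m <- small_model()
  inp <- helix_inputs(48, sigma = 0.3, seed = 9)
  o <- forward(m, inp$seq, inp$cloud)
  ent <- mean(-rowSums(exp(o$log_probs) * o$log_probs))
  expect_gte(ent, 0.9 * log(33))
})

test_that("log-probabilities are rigid-transform invariant (contract 1e-4)", {
  m <- small_model()
  inp <- helix_inputs(40, sigma = 0.3, seed = 5)
  expect_equal(invariance_check(m, inp$seq, inp$cloud,
                                rigid_transform()), 0)
  devs <- vapply(1:30, function(s)
    invariance_check(m, inp$seq, inp$cloud, random_rigid_transform(s)), 0.0)
  expect_lt(max(devs), 1e-4)
})

test_that("recovered coordinates are equivariant (contract 1e-3 A)", {
  m <- small_model()
  inp <- helix_inputs(40, sigma = 0.3, seed = 5)
  devs <- vapply(1:30, function(s)
    equivariance_check(m, inp$seq, inp$cloud, random_rigid_transform(s)),
    0.0)
  expect_lt(max(devs), 1e-3)
})

test_that("representations are invariant and pool over non-pad positions", {
  m <- small_model()
  inp <- helix_inputs(20, sigma = 0.2, seed = 3)
  cp <- crop_or_pad(inp$cloud, inp$seq, context = 40, seed = 1)
  r <- extract_representations(m, cp$seq, cp$cloud)
  real <- which(!cp$seq$pad)
  expect_equal(r$pooled_rep, colMeans(r$residue_reps[real, ]))
  t <- random_rigid_transform(4)
  r2 <- extract_representations(m, cp$seq,
                                apply_transform(cp$cloud, t))
  expect_lt(max(abs(r$residue_reps[real, ] - r2$residue_reps[real, ])),
            1e-4)
  expect_lt(max(abs(r$pooled_rep - r2$pooled_rep)), 1e-4)
})

test_that("sequence-only degenerate mode works when all points are masked", {
  m <- small_model()
  inp <- helix_inputs(25, sigma = 0.2, seed = 6)
  blind <- inp$cloud
  blind$coord_mask[] <- FALSE
  o <- forward(m, inp$seq, blind)
  expect_lt(max(abs(rowSums(exp(o$log_probs)) - 1)), 1e-5)
  expect_true(all(is.finite(o$log_probs)))
})

test_that("parameter count follows shape arithmetic and scaling laws", {
  cfg <- model_config(K = 8, encoder_layers = 1, encoder_heads = 2,
                      context = 16, knn = 4, struct_heads = 2,
                      struct_layers = 1, ffn_mult = 2)
  K <- 8; ffK <- 16; V <- 33
  block <- 2 * K +                    # ln1
    4 * (K * K + K) +                 # attention
    2 * K +                           # ln2
    (K * ffK + ffK) + (ffK * K + K)   # ffn
  expected <- V * K +                 # token embedding
    (2 * 4 * K + K) + K +             # struct proj (F=2*knn=8) + null
    block +                           # struct block
    block +                           # encoder block
    2 * K +                           # final LN
    (K * K + K) + 2 * K + (K * V + V) +        # sequence decoder
    (K * K + K) + (K * K + K) + (K * 3 + 3)    # structure decoder
  expect_equal(count_parameters(cfg), expected)
  expect_equal(count_parameters(cfg, include_positional = TRUE),
               expected + 16 * K)
  # doubling K more than doubles the count
  cfg2 <- model_config(K = 16, encoder_layers = 1, encoder_heads = 2,
                       context = 16, knn = 4, struct_heads = 2,
                       ffn_mult = 2)
  expect_gt(count_parameters(cfg2), 2 * count_parameters(cfg))
  # independent of context
  cfg3 <- model_config(K = 8, encoder_layers = 1, encoder_heads = 2,
                       context = 64, knn = 4, struct_heads = 2,
                       ffn_mult = 2)
  expect_equal(count_parameters(cfg3), count_parameters(cfg))
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(K = 8, encoder_layers = 1, encoder_heads = 2,
                      context = 16, knn = 4, struct_heads = 2,
                      ffn_mult = 2)
  m <- init_model(cfg, seed = 3)
  h <- make_helix(12, sigma = 0.4, seed = 9)
  ex <- make_training_example(h$record, h$structure,
                              config = list(context_size = 16), seed = 4)
  # fixed random cotangents make the surrogate loss linear in the outputs,
  # avoiding the Chamfer argmin's non-differentiable points
  set.seed(10)
  dlp <- matrix(rnorm(16 * 33, sd = 0.1), 16, 33)
  dco <- matrix(rnorm(16 * 3, sd = 0.1), 16, 3)
  surrogate <- function(model) {
    o <- forward(model, ex$seq, ex$cloud)
    sum(dlp * o$log_probs) + sum(dco * o$recovered_coords)
  }
  out <- forward(m, ex$seq, ex$cloud, want_cache = TRUE)
  G <- mutpoint:::model_backward(m, out, dlp, dco)
  eps <- 1e-5
  probe <- function(get, set) {
    arr <- get(m$params)
    ga <- get(G)
    idx <- seq_len(min(3, length(arr)))
    for (i in idx) {
      mp <- m; mp$params <- set(m$params, i, arr[i] + eps)
      mm <- m; mm$params <- set(m$params, i, arr[i] - eps)
      num <- (surrogate(mp) - surrogate(mm)) / (2 * eps)
      expect_lt(abs(num - ga[i]), 1e-5 + 1e-3 * abs(num))
    }
  }
  probe(function(p) p$enc[[1]]$attn$Wq,
        function(p, i, v) { p$enc[[1]]$attn$Wq[i] <- v; p })
  probe(function(p) p$enc[[1]]$ffn$W1,
        function(p, i, v) { p$enc[[1]]$ffn$W1[i] <- v; p })
  probe(function(p) p$struct$proj$W,
        function(p, i, v) { p$struct$proj$W[i] <- v; p })
  probe(function(p) p$tok_emb,
        function(p, i, v) { p$tok_emb[i] <- v; p })
  probe(function(p) p$str_dec$W3,
        function(p, i, v) { p$str_dec$W3[i] <- v; p })
  probe(function(p) p$seq_dec$W2,
        function(p, i, v) { p$seq_dec$W2[i] <- v; p })
  probe(function(p) p$ln_f$g,
        function(p, i, v) { p$ln_f$g[i] <- v; p })
})

test_that("checkpoints round-trip and refuse corrupted configs", {
  m <- small_model()
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$params, m$params)
  inp <- helix_inputs(20, sigma = 0.2, seed = 2)
  expect_equal(forward(m2, inp$seq, inp$cloud)$log_probs,
               forward(m, inp$seq, inp$cloud)$log_probs)
  # tamper with the stored config -> hash refusal
  ck <- readRDS(f)
  ck$config$K <- 128
  f2 <- tempfile(fileext = ".rds")
  saveRDS(ck, f2)
  expect_error(load_checkpoint(f2), "hash")
})

test_that("tok_emb gradient for the first 3 entries is handled", {
  # specials can receive zero gradient; the probe above uses entries that
  # may be unused tokens, so check a used token explicitly
  cfg <- model_config(K = 8, encoder_layers = 1, encoder_heads = 2,
                      context = 16, knn = 4, struct_heads = 2,
                      ffn_mult = 2)
  m <- init_model(cfg, seed = 3)
  h <- make_helix(12, sigma = 0.4, seed = 9)
  ex <- make_training_example(h$record, h$structure,
                              config = list(context_size = 16), seed = 4)
  out <- forward(m, ex$seq, ex$cloud, want_cache = TRUE)
  dlp <- mutpoint:::.ce_grad(out$log_probs, ex$token_targets)
  G <- mutpoint:::model_backward(m, out, dlp, NULL)
  used <- unique(ex$seq$tokens)
  expect_gt(max(abs(G$tok_emb[used, ])), 0)
  unused <- setdiff(seq_len(33), used)
  expect_equal(max(abs(G$tok_emb[unused, ])), 0)
})
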