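test_that("cross-entropy closed forms", {
  L <- 10
  targets <- data.frame(position = c(2L, 5L), token = c(6L, 11L))
  # probability 1 on the true token -> 0 loss
  lp <- matrix(-1e9, L, 33)
  lp[cbind(targets$position, targets$token)] <- 0
  expect_equal(ce_loss(lp, targets), 0)
  # uniform -> ln 33
  lpu <- matrix(log(1 / 33), L, 33)
  expect_equal(ce_loss(lpu, targets), log(33))
  expect_equal(log(33), 3.4965, tolerance = 1e-4)
  # unmasked positions never contribute
  lpu2 <- lpu
  lpu2[1, ] <- rnorm(33)
  expect_equal(ce_loss(lpu2, targets), ce_loss(lpu, targets))
  expect_error(ce_loss(lpu, targets[0, ]), "at least one")
})

test_that("Chamfer loss closed forms and oracle agreement", {
  set.seed(2)
  # well-separated truth, prediction = truth + unit shift -> exactly 1
  truth <- cbind(seq(0, 27, by = 3), 0, 0)  # gaps 3 A > 2 A
  targets <- data.frame(index = 1:10, x = truth[, 1], y = truth[, 2],
                        z = truth[, 3])
  pred <- truth + matrix(c(1, 0, 0), 10, 3, byrow = TRUE)
  expect_equal(cd_loss(pred, targets), 1.0)
  expect_equal(chamfer_oracle(pred, truth), 1.0)
  # perfect recovery
  expect_equal(cd_loss(truth, targets), 0)
  # random 8-point sets against the brute-force oracle
  for (seed in 1:5) {
    set.seed(seed)
    pred <- matrix(rnorm(24, sd = 4), 8, 3)
    tr <- matrix(rnorm(24, sd = 4), 8, 3)
    tg <- data.frame(index = 1:8, x = tr[, 1], y = tr[, 2], z = tr[, 3])
    expect_lt(abs(cd_loss(pred, tg) - chamfer_oracle(pred, tr)), 1e-9)
  }
})

test_that("Chamfer loss is invariant under joint rigid transforms", {
  set.seed(5)
  pred <- matrix(rnorm(24), 8, 3)
  tr <- matrix(rnorm(24), 8, 3)
  tg <- data.frame(index = 1:8, x = tr[, 1], y = tr[, 2], z = tr[, 3])
  base <- cd_loss(pred, tg)
  t <- random_rigid_transform(3)
  pred2 <- sweep(pred %*% t(t$rotation), 2, t$translation, `+`)
  tr2 <- sweep(tr %*% t(t$rotation), 2, t$translation, `+`)
  tg2 <- data.frame(index = 1:8, x = tr2[, 1], y = tr2[, 2], z = tr2[, 3])
  expect_lt(abs(cd_loss(pred2, tg2) - base), 1e-9)
})

test_that("learning-rate schedule: warm-up, decay, continuity", {
  sched <- schedule_config()
  expect_equal(lr_at(0, sched), 0)
  expect_equal(lr_at(10000, sched), 1e-4)
  expect_equal(lr_at(40000, sched), 5e-5)
  expect_equal(lr_at(5000, sched), 5e-5)  # linear warm-up midpoint
  # continuity at the boundary
  expect_lt(abs(lr_at(10001, sched) - lr_at(10000, sched)), 1e-8)
  # monotone decay afterwards
  lrs <- vapply(seq(10000, 50000, by = 5000), lr_at, 0.0, sched = sched)
  expect_true(all(diff(lrs) < 0))
})

test_that("total loss is ce + cd at unit weights", {
  m <- small_model()
  h <- make_helix(20, sigma = 0.3, seed = 14)
  ex <- make_training_example(h$record, h$structure,
                              config = list(context_size = 32), seed = 2)
  o <- forward(m, ex$seq, ex$cloud)
  lb <- training_loss(o, ex)
  expect_equal(lb$total, lb$ce + lb$cd)
  expect_equal(lb$n_token_targets, nrow(ex$token_targets))
  lb2 <- training_loss(o, ex, ce_weight = 2, cd_weight = 0.5)
  expect_equal(lb2$total, 2 * lb$ce + 0.5 * lb$cd)
})

test_that("a short training run reduces the loss deterministically", {
  set <- make_geometry_coded_set(10, length = 24, sigma = 0.2, seed = 17)
  examples <- lapply(seq_along(set), function(i)
    make_training_example(set[[i]]$record, set[[i]]$structure,
                          config = list(context_size = 24), seed = 50 + i))
  cfg <- model_config(K = 16, encoder_layers = 1, encoder_heads = 2,
                      context = 24, knn = 6, struct_heads = 2, ffn_mult = 2)
  m <- init_model(cfg, seed = 1)
  sched <- schedule_config(base_lr = 1e-3, warmup_steps = 5, batch_size = 4,
                           total_steps = 40)
  fit <- train_model(m, examples, sched, seed = 3)
  expect_lt(utils::tail(fit$log$total, 1), fit$log$total[1])
  expect_equal(nrow(fit$log), 40L)
  # identical seeds -> identical loss curves
  fit2 <- train_model(m, examples, sched, seed = 3)
  expect_identical(fit$log, fit2$log)
  # checkpoint written when requested
  ckpt <- tempfile(fileext = ".rds")
  fit3 <- train_model(m, examples,
                      schedule_config(base_lr = 1e-3, warmup_steps = 2,
                                      batch_size = 4, total_steps = 3),
                      seed = 3, checkpoint = ckpt)
  expect_true(file.exists(ckpt))
  m2 <- load_checkpoint(ckpt)
  expect_equal(m2$params, fit3$model$params)
})

test_that("masked-LM fine-tuning: zero epochs is identity, losses settle", {
  set <- make_geometry_coded_set(6, length = 20, sigma = 0.2, seed = 23)
  examples <- lapply(seq_along(set), function(i)
    make_training_example(set[[i]]$record, set[[i]]$structure,
                          config = list(context_size = 20), seed = 70 + i))
  cfg <- model_config(K = 16, encoder_layers = 1, encoder_heads = 2,
                      context = 20, knn = 6, struct_heads = 2, ffn_mult = 2)
  m <- init_model(cfg, seed = 2)
  ft0 <- finetune_masked_lm(m, examples, epochs = 0)
  expect_identical(ft0$model$params, m$params)
  ft <- finetune_masked_lm(m, examples, epochs = 3, lr = 1e-3, seed = 5)
  em <- tapply(ft$log$total, ft$log$epoch, mean)
  expect_true(all(diff(em) <= 1e-8))
  # seed determinism
  ft2 <- finetune_masked_lm(m, examples, epochs = 3, lr = 1e-3, seed = 5)
  expect_identical(ft$log, ft2$log)
})
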