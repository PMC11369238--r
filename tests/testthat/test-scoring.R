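# hand-built log-probability table over a tiny reference
hand_table <- function(ref = "AGV") {
  L <- nchar(ref)
  lp <- matrix(log(1 / 33), L, 33)
  attr(lp, "reference") <- ref
  class(lp) <- c("logit_table", class(lp))
  lp
}

test_that("variant notation parses and validates", {
  v <- parse_variant("S72R")
  expect_equal(v$position, 72L)
  expect_equal(v$wt, "S"); expect_equal(v$mt, "R")
  mv <- parse_variant("D191A/S72R/K84R")
  expect_equal(nrow(mv), 3L)
  expect_equal(mv$position, c(72L, 84L, 191L))  # sorted
  expect_equal(format(mv), "S72R/K84R/D191A")
  expect_equal(nrow(parse_variant("")), 0L)
  expect_equal(format(parse_variant("WT")), "WT")
  expect_error(parse_variant("S72"), "parse")
  expect_error(variant(c(5, 5), c("A", "G"), c("V", "L")), "distinct")
  expect_error(variant(1, "A", "A"), "differ")
})

test_that("fitness scoring identities: WT zero, arithmetic, additivity", {
  ids <- stats::setNames(seq_len(33), token_alphabet())
  tab <- hand_table("AGV")
  expect_equal(score_variant(tab, parse_variant("")), 0.0)
  # hand-built: log p(mt) = -1, log p(wt) = -2 at position 2
  tab[2, ids[["L"]]] <- -1.0
  tab[2, ids[["G"]]] <- -2.0
  expect_equal(score_variant(tab, "G2L"), 1.0)
  # additivity of a double mutant
  tab[1, ids[["W"]]] <- -0.5
  tab[1, ids[["A"]]] <- -3.0
  expect_equal(score_variant(tab, "A1W/G2L"),
               score_variant(tab, "A1W") + score_variant(tab, "G2L"))
  # antisymmetry on the same table
  expect_equal(score_variant(tab, "G2L"),
               -(tab[2, ids[["G"]]] - tab[2, ids[["L"]]]))
  # wild-type mismatch errors name the position
  expect_error(score_variant(tab, "V2L"), "position 2")
  expect_error(score_variant(tab, "A9V"), "range")
})

test_that("pathogenicity follows the shifted sigmoid with strict threshold", {
  ids <- stats::setNames(seq_len(33), token_alphabet())
  tab <- hand_table("AGV")
  # gap exactly tau -> P = 0.5, NOT pathogenic (strict inequality)
  tab[1, ids[["A"]]] <- -1
  tab[1, ids[["V"]]] <- -7      # logit_w - logit_m = 6
  pg <- pathogenicity(tab, 1, "A", "V", tau = 6)
  expect_equal(pg$probability, 0.5)
  expect_false(pg$pathogenic)
  # gap tau + ln 9 -> P = 0.9, pathogenic
  tab[1, ids[["V"]]] <- -1 - 6 - log(9)
  pg2 <- pathogenicity(tab, 1, "A", "V", tau = 6)
  expect_equal(pg2$probability, 0.9)
  expect_true(pg2$pathogenic)
  # tau = 0 alternative convention
  tab[1, ids[["V"]]] <- -1 - log(9)
  pg3 <- pathogenicity(tab, 1, "A", "V", tau = 0)
  expect_equal(pg3$probability, 0.9)
  # monotone in the logit gap, strictly inside (0, 1)
  gaps <- seq(-10, 10, by = 2)
  ps <- vapply(gaps, function(g) {
    tab[1, ids[["V"]]] <- tab[1, ids[["A"]]] - g
    pathogenicity(tab, 1, "A", "V")$probability
  }, 0.0)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("fold-change labelling applies the strict 1.2 / 0.8 rule", {
  expect_equal(label_fold_change(1.56), "positive")
  expect_equal(label_fold_change(0.7), "negative")
  expect_equal(label_fold_change(1.0), "excluded")
  expect_equal(label_fold_change(c(1.2, 0.8)), c("excluded", "excluded"))
  expect_error(label_fold_change(-0.1), "non-negative")
})

test_that("library scoring equals per-variant scoring and ranks stably", {
  rec <- make_helix(30, seed = 41)$record
  land <- make_landscape(rec, seed = 6)
  tab <- make_landscape_table(land)
  lib <- enumerate_saturation(rec)
  st <- score_library(tab, lib)
  expect_equal(nrow(st), 30 * 19)
  # spot-check 50 random variants against score_variant
  set.seed(8)
  for (i in sample(nrow(st), 50))
    expect_equal(st$score[i], score_variant(tab, st$variant[i]))
  # singleton library
  one <- st[st$rank == 1, ]
  st1 <- score_library(tab, data.frame(variant = one$variant))
  expect_equal(st1$score, one$score)
  # ranking invariant to a constant shift of every log-prob row
  tab2 <- tab + 0.37
  attr(tab2, "reference") <- attr(tab, "reference")
  class(tab2) <- class(tab)
  st2 <- score_library(tab2, lib)
  expect_equal(st2$rank, st$rank)
})

test_that("WT-marginal and masked-marginal tables both drive the scorer", {
  m <- small_model()
  inp <- helix_inputs(15, sigma = 0.2, seed = 44)
  twt <- logit_table(m, inp$record, inp$structure, mode = "wt")
  tmm <- logit_table(m, inp$record, inp$structure, mode = "masked")
  expect_equal(dim(twt), c(15, 33))
  expect_equal(dim(tmm), c(15, 33))
  expect_false(identical(twt, tmm))
  v <- sprintf("%s%dV", substr(inp$record$sequence, 3, 3), 3)
  if (substr(inp$record$sequence, 3, 3) != "V") {
    expect_true(is.finite(score_variant(twt, v)))
    expect_true(is.finite(score_variant(tmm, v)))
  }
})

test_that("binary fine-tuning fits separable labels and reports the split", {
  cfg <- model_config(K = 16, encoder_layers = 1, encoder_heads = 2,
                      context = 32, knn = 8, struct_heads = 2, ffn_mult = 2)
  m <- init_model(cfg, seed = 9)
  inp <- helix_inputs(30, sigma = 0.2, seed = 51)
  # realizable labels: sign of the initial model's own score with margin
  tab <- logit_table(m, inp$record, inp$structure)
  lib <- enumerate_saturation(inp$record)
  st <- score_library(tab, lib)
  ord <- st[order(-st$score), ]
  pos <- ord[1:14, ]                      # strongest positive scores
  neg <- ord[(nrow(ord) - 12):nrow(ord), ]  # strongest negative scores
  expect_gt(min(pos$score), 0)
  expect_lt(max(neg$score), 0)
  labeled <- data.frame(variant = c(pos$variant, neg$variant),
                        label = c(rep("positive", 14), rep("negative", 13)))
  ft <- finetune_binary(m, inp$record, inp$structure, labeled,
                        epochs = 40, lr = 1e-3, seed = 3)
  expect_equal(ft$report$n_train, 22L)   # round(0.8 * 27)
  expect_equal(ft$report$n_val, 5L)
  expect_lt(ft$report$loss_last, ft$report$loss_first)
  expect_equal(ft$report$val_accuracy, 1.0)
})

test_that("binary fine-tuning refuses a one-class training split", {
  m <- small_model()
  inp <- helix_inputs(20, sigma = 0.2, seed = 52)
  ref <- strsplit(inp$record$sequence, "")[[1]]
  mt <- ifelse(ref[1:6] == "A", "G", "A")
  labeled <- data.frame(variant = sprintf("%s%d%s", ref[1:6], 1:6, mt),
                        label = rep("positive", 6))
  expect_error(finetune_binary(m, inp$record, inp$structure, labeled),
               "each class")
})
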