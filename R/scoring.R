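#' Parse variant notation
#'
#' Accepts `"S72R"`-style single substitutions and slash-joined multi-site
#' variants (`"D191A/S72R/K84R"`). Positions are 1-based internal residue
#' numbers.
#'
#' @param text Variant string; the empty string denotes the wild type.
#' @return Object of class `variant`: data.frame with `position`, `wt`,
#'   `mt`.
#' @export
parse_variant <- function(text) {
  text <- trimws(text)
  if (!nzchar(text) || identical(toupper(text), "WT"))
    return(variant(integer(0), character(0), character(0)))
  parts <- strsplit(text, "/", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", parts))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad) > 0L)
    stop("cannot parse variant token '", parts[bad[1]], "'")
  variant(position = as.integer(vapply(m, `[[`, "", 3L)),
          wt = toupper(vapply(m, `[[`, "", 2L)),
          mt = toupper(vapply(m, `[[`, "", 4L)))
}

#' Construct a variant
#'
#' @param position Integer vector of 1-based positions (distinct).
#' @param wt,mt Character vectors of wild-type and mutant residues
#'   (`wt[i] != mt[i]`).
#' @export
variant <- function(position, wt, mt) {
  position <- as.integer(position)
  stopifnot(length(position) == length(wt), length(wt) == length(mt))
  if (anyDuplicated(position)) stop("variant positions must be distinct")
  if (any(wt == mt)) stop("wt and mt must differ at every substitution")
  ord <- order(position)
  structure(data.frame(position = position[ord], wt = wt[ord], mt = mt[ord],
                       stringsAsFactors = FALSE),
            class = c("variant", "data.frame"))
}

#' @export
format.variant <- function(x, ...) {
  if (nrow(x) == 0L) return("WT")
  paste(sprintf("%s%d%s", x$wt, x$position, x$mt), collapse = "/")
}

#' @export
print.variant <- function(x, ...) {
  cat("<variant>", format(x), "\n")
  invisible(x)
}

#' Per-position log-probability table from one forward pass
#'
#' Feeds the intact wild-type sequence and structure through the model once
#' and returns the L x 33 log-probability rows (WT-marginal scoring, the
#' default). `mode = "masked"` instead masks position t and runs one pass
#' per position, reading row t from each pass (masked-marginal).
#'
#' @param model A `mutpoint_model`.
#' @param record A `protein_record` (the reference).
#' @param structure Optional matching `structure_model`; when `NULL` the
#'   model runs in sequence-only degenerate mode.
#' @param mode `"wt"` (default) or `"masked"`.
#' @return Object of class `logit_table`: L x 33 matrix with the reference
#'   sequence attached as attribute `reference`.
#' @export
logit_table <- function(model, record, structure = NULL,
                        mode = c("wt", "masked")) {
  mode <- match.arg(mode)
  seq <- tokenize_sequence(record$sequence)
  L <- record$L
  cloud <- if (is.null(structure)) {
    protein_cloud(matrix(0, L, 3), strsplit(record$sequence, "")[[1]],
                  coord_mask = rep(FALSE, L))
  } else from_structure(structure)
  if (length(cloud$P) != L)
    stop("structure length ", length(cloud$P), " != sequence length ", L)
  sp <- token_specials()
  if (mode == "wt") {
    tab <- forward(model, seq, cloud)$log_probs
  } else {
    tab <- matrix(NA_real_, L, model$config$vocab)
    for (t in seq_len(L)) {
      toks <- seq$tokens
      toks[t] <- sp$mask
      tab[t, ] <- forward(model, tok_seq(toks, seq$pad), cloud)$log_probs[t, ]
    }
  }
  rownames(tab) <- as.character(seq_len(L))
  attr(tab, "reference") <- record$sequence
  class(tab) <- c("logit_table", class(tab))
  tab
}

.check_wt <- function(table, v) {
  ref <- strsplit(attr(table, "reference"), "")[[1]]
  if (nrow(v) == 0L) return(invisible(TRUE))
  if (any(v$position < 1L | v$position > length(ref)))
    stop("variant position out of range 1..", length(ref))
  bad <- which(ref[v$position] != v$wt)
  if (length(bad) > 0L)
    stop("wild-type mismatch at position ", v$position[bad[1]],
         ": reference has '", ref[v$position[bad[1]]], "', variant says '",
         v$wt[bad[1]], "'")
  invisible(TRUE)
}

#' Zero-shot fitness score of a variant
#'
#' The log-likelihood ratio read from one wild-type log-probability table:
#' the sum over mutated positions of `log p(mt) - log p(wt)`. The wild type
#' scores exactly 0 and multi-site scores are additive in their single-site
#' constituents by construction.
#'
#' @param table A `logit_table`.
#' @param v A `variant` (or variant string).
#' @return Scalar score.
#' @export
score_variant <- function(table, v) {
  if (is.character(v)) v <- parse_variant(v)
  .check_wt(table, v)
  if (nrow(v) == 0L) return(0.0)
  ids <- .token_ids()
  sum(table[cbind(v$position, unname(ids[v$mt]))] -
      table[cbind(v$position, unname(ids[v$wt]))])
}

#' Pathogenicity probability of a single substitution
#'
#' `P = sigmoid(logit_wt - logit_mt - tau)` at position `i`, with `tau = 6`
#' by default; the variant is classified pathogenic when `P > 0.5`
#' (strictly). `tau = 0` reproduces the alternative baseline convention.
#' Because both logits come from the same row, log-probabilities and raw
#' logits give identical differences.
#'
#' @param table A `logit_table`.
#' @param position 1-based position.
#' @param w Wild-type residue letter.
#' @param m Mutant residue letter.
#' @param tau Threshold offset (default 6).
#' @return List with `probability` in (0, 1) and logical `pathogenic`.
#' @export
pathogenicity <- function(table, position, w, m, tau = 6) {
  v <- variant(position, w, m)
  .check_wt(table, v)
  ids <- .token_ids()
  gap <- table[position, unname(ids[w])] - table[position, unname(ids[m])]
  p <- stats::plogis(gap - tau)
  list(probability = unname(p), pathogenic = unname(p > 0.5))
}

#' Label an experimental fold change
#'
#' Fold change > 1.2 is a positive sample, < 0.8 negative; the closed
#' interval `[0.8, 1.2]` is excluded from fine-tuning.
#'
#' @param fc Non-negative fold change (variant activity / WT activity).
#' @return `"positive"`, `"negative"` or `"excluded"` (vectorized).
#' @export
label_fold_change <- function(fc) {
  if (any(fc < 0)) stop("fold change must be non-negative")
  ifelse(fc > 1.2, "positive", ifelse(fc < 0.8, "negative", "excluded"))
}

#' Score a variant library from one table
#'
#' Because scores are per-position sums over a single wild-type table,
#' whole libraries are scored by arithmetic over precomputed per-position
#' gains without further forward passes. Ranks are dense over descending
#' score with ties broken by variant string.
#'
#' @param table A `logit_table`.
#' @param lib A `variant_library` (materialized) or data.frame with
#'   `variant` strings.
#' @return A `score_table`: data.frame with `variant`, `score`, `rank` and
#'   metadata attribute.
#' @export
score_library <- function(table, lib) {
  df <- if (inherits(lib, "variant_library")) lib$variants else lib
  stopifnot(is.data.frame(df), "variant" %in% names(df))
  ref <- strsplit(attr(table, "reference"), "")[[1]]
  ids <- .token_ids()
  # per-position gain matrix: gain[p, aa] = lp(aa) - lp(wt at p)
  aa_cols <- unname(ids[AA_LETTERS])
  gains <- table[, aa_cols, drop = FALSE] -
    table[cbind(seq_along(ref), unname(ids[ref]))]
  colnames(gains) <- AA_LETTERS
  score_one <- function(s) {
    v <- parse_variant(s)
    .check_wt(table, v)
    if (nrow(v) == 0L) return(0.0)
    sum(gains[cbind(v$position, match(v$mt, AA_LETTERS))])
  }
  scores <- vapply(df$variant, score_one, 0.0, USE.NAMES = FALSE)
  out <- data.frame(variant = df$variant, score = scores,
                    stringsAsFactors = FALSE)
  ord <- order(-out$score, out$variant)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "metadata") <- list(reference_hash = config_hash(paste(ref,
                                                                   collapse = "")),
                                n_variants = nrow(out))
  class(out) <- c("score_table", class(out))
  out
}

#' Fine-tune on binary fold-change labels
#'
#' Optimizes the binary cross-entropy
#' `-(y log P(x) + (1 - y) log(1 - P(x)))` with
#' `P(x) = sigmoid(sum_t (logit_mt - logit_wt))` over the labeled variants,
#' where the logits come from a forward pass of the intact wild type. The
#' labeled set is split `round(split * n)` / remainder into training and
#' validation with a seeded shuffle; training requires at least two samples
#' per class.
#'
#' @param model A `mutpoint_model`.
#' @param record Reference `protein_record`.
#' @param structure Matching `structure_model` (or `NULL`).
#' @param labeled Data.frame with `variant` strings and `label`
#'   (`"positive"`/`"negative"` or 1/0).
#' @param split Training fraction (default 0.8).
#' @param epochs Gradient steps over the full training batch (default 30).
#' @param lr Learning rate (default 1e-4).
#' @param seed Integer seed for the shuffle.
#' @return List with `model`, `report` (data.frame: split sizes, losses,
#'   validation accuracy) and `splits` (row indices).
#' @export
finetune_binary <- function(model, record, structure, labeled, split = 0.8,
                            epochs = 30, lr = 1e-4, seed = 1) {
  stopifnot(is.data.frame(labeled), all(c("variant", "label") %in%
                                        names(labeled)))
  y <- labeled$label
  if (is.character(y)) y <- as.integer(y == "positive")
  y <- as.numeric(y)
  n <- nrow(labeled)
  n_train <- round(split * n)
  ord <- with_seed(child_seed(seed, "ftsplit"), sample.int(n))
  tr <- ord[seq_len(n_train)]
  va <- ord[setdiff(seq_len(n), seq_len(n_train))]
  if (length(unique(y[tr])) < 2L || min(table(y[tr])) < 2L)
    stop("training split must contain at least two samples of each class")

  seq <- tokenize_sequence(record$sequence)
  cloud <- if (is.null(structure)) {
    protein_cloud(matrix(0, record$L, 3),
                  strsplit(record$sequence, "")[[1]],
                  coord_mask = rep(FALSE, record$L))
  } else from_structure(structure)
  ids <- .token_ids()
  vars <- lapply(labeled$variant, parse_variant)

  state <- NULL
  var_score <- function(lp, v)
    sum(lp[cbind(v$position, unname(ids[v$mt]))] -
        lp[cbind(v$position, unname(ids[v$wt]))])
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    out <- forward(model, seq, cloud, want_cache = TRUE)
    lp <- out$log_probs
    dlp <- matrix(0, nrow(lp), ncol(lp))
    loss <- 0
    for (i in tr) {
      v <- vars[[i]]
      s <- var_score(lp, v)
      p <- stats::plogis(s)
      eps <- 1e-12
      loss <- loss - (y[i] * log(p + eps) + (1 - y[i]) * log(1 - p + eps))
      dscore <- (p - y[i]) / length(tr)
      mt_idx <- cbind(v$position, unname(ids[v$mt]))
      wt_idx <- cbind(v$position, unname(ids[v$wt]))
      dlp[mt_idx] <- dlp[mt_idx] + dscore
      dlp[wt_idx] <- dlp[wt_idx] - dscore
    }
    losses[ep] <- loss / length(tr)
    g <- model_backward(model, out, dlp, NULL)
    gn <- tree_global_norm(g)
    if (gn > 1) g <- tree_scale(g, 1 / gn)
    up <- .adam_step(model$params, g, state, lr, c(0.9, 0.999))
    model$params <- up$params
    state <- up$state
  }
  # validation
  lp <- forward(model, seq, cloud)$log_probs
  preds <- vapply(va, function(i) stats::plogis(var_score(lp, vars[[i]])), 0.0)
  acc <- if (length(va) > 0) mean((preds > 0.5) == (y[va] == 1)) else NA_real_
  list(model = model,
       report = data.frame(n_train = length(tr), n_val = length(va),
                           loss_first = losses[1],
                           loss_last = losses[epochs],
                           val_accuracy = acc),
       splits = list(train = tr, val = va))
}
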