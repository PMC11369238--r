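#' Attention-derived residue saliency
#'
#' Scores each residue by the attention it receives, averaged over all
#' encoder layers, heads and (real) query positions. Rows of the attention
#' matrices are renormalized over real positions before averaging so that
#' pad/special positions never dilute the scores; the resulting scores sum
#' to 1 over real residues. Ranking is by descending score, ties broken by
#' lower position.
#'
#' @param output A `model_output` from [forward()] (attentions present).
#' @param direction `"received"` (column mean, default) or `"paid"` (row
#'   mean).
#' @return Object of class `residue_saliency`: list with numeric `score`
#'   (length L, `NA` at pad positions) and integer `ranking` over real
#'   positions, best first.
#' @export
attention_saliency <- function(output, direction = c("received", "paid")) {
  direction <- match.arg(direction)
  if (is.null(output$attentions) || length(output$attentions) == 0L)
    stop("model output carries no attention tensors")
  real <- which(!output$pad)
  L <- length(output$pad)
  acc <- matrix(0, length(real), length(real))
  n <- 0L
  for (layer in output$attentions) {
    for (A in layer) {
      Ar <- A[real, real, drop = FALSE]
      Ar <- Ar / rowSums(Ar)       # renormalize over real keys
      acc <- acc + Ar
      n <- n + 1L
    }
  }
  Abar <- acc / n
  s <- if (direction == "received") colMeans(Abar) else rowMeans(Abar)
  score <- rep(NA_real_, L)
  score[real] <- s
  ranking <- real[order(-s, real)]
  structure(list(score = score, ranking = ranking),
            class = "residue_saliency")
}

#' @export
print.residue_saliency <- function(x, ...) {
  cat(sprintf("<residue_saliency> %d residues, top: %s\n",
              sum(!is.na(x$score)),
              paste(utils::head(x$ranking, 5), collapse = ", ")))
  invisible(x)
}

#' Top-1 hit ratio
#'
#' Fraction of proteins whose rank-1 residue is in the truth set. Proteins
#' with an empty truth set are skipped with a warning.
#'
#' @param rankings List of `residue_saliency` (or integer rankings).
#' @param truths List of integer truth sets (functional-site positions).
#' @return Scalar in `[0, 1]`.
#' @export
top1_hit_ratio <- function(rankings, truths) {
  stopifnot(length(rankings) == length(truths))
  hits <- logical(0)
  for (i in seq_along(rankings)) {
    r <- if (inherits(rankings[[i]], "residue_saliency"))
      rankings[[i]]$ranking else rankings[[i]]
    if (length(truths[[i]]) == 0L) {
      warning("protein ", i, " has an empty truth set; skipped")
      next
    }
    hits <- c(hits, r[1] %in% truths[[i]])
  }
  if (length(hits) == 0L) stop("no proteins with non-empty truth sets")
  mean(hits)
}

#' Normalized discounted cumulative gain (binary relevance)
#'
#' `DCG = sum over ranks r of rel(r) / log2(r + 1)` divided by the ideal
#' DCG (all relevant residues first), optionally truncated at `cutoff`.
#'
#' @param ranking A `residue_saliency` or integer ranking (best first).
#' @param truth Integer set of relevant positions (non-empty).
#' @param cutoff Optional rank cutoff.
#' @return Scalar in `[0, 1]`.
#' @export
ndcg <- function(ranking, truth, cutoff = NULL) {
  if (inherits(ranking, "residue_saliency")) ranking <- ranking$ranking
  stopifnot(length(truth) >= 1L)
  n <- length(ranking)
  if (!is.null(cutoff)) n <- min(n, cutoff)
  rel <- as.numeric(ranking[seq_len(n)] %in% truth)
  dcg <- sum(rel / log2(seq_len(n) + 1))
  n_ideal <- min(length(truth), n)
  idcg <- sum(1 / log2(seq_len(n_ideal) + 1))
  dcg / idcg
}

#' Mean reciprocal rank
#'
#' Mean over proteins of `1 / rank` of the first relevant residue; a
#' protein with no relevant residue ranked contributes 0.
#'
#' @inheritParams top1_hit_ratio
#' @return Scalar in `[0, 1]`.
#' @export
mrr <- function(rankings, truths) {
  stopifnot(length(rankings) == length(truths))
  rr <- numeric(length(rankings))
  for (i in seq_along(rankings)) {
    r <- if (inherits(rankings[[i]], "residue_saliency"))
      rankings[[i]]$ranking else rankings[[i]]
    pos <- which(r %in% truths[[i]])
    rr[i] <- if (length(pos) == 0L) 0 else 1 / pos[1]
  }
  mean(rr)
}
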