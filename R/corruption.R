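#' Mask a tokenized sequence (BERT-style 80/10/10)
#'
#' Selects exactly `round(ratio * n_nonpad)` positions (at least one)
#' uniformly without replacement among the non-pad positions. Each selected
#' position is independently replaced by the mask token (probability
#' `probs[1]`), by a uniformly chosen *alternate* canonical residue token
#' different from the original (`probs[2]`), or kept unchanged (`probs[3]`).
#' The original token at every selected position is recorded as a target.
#'
#' @param seq A `tok_seq`.
#' @param ratio Fraction of non-pad tokens to select (default 0.15).
#' @param probs Length-3 numeric `(mask, random, keep)` summing to 1.
#' @param seed Integer seed.
#' @return List with `seq` (corrupted `tok_seq`) and `targets`, a data.frame
#'   of `position` and original `token`.
#' @export
mask_sequence <- function(seq, ratio = 0.15, probs = c(0.8, 0.1, 0.1),
                          seed = 1) {
  stopifnot(inherits(seq, "tok_seq"), ratio > 0, ratio < 1,
            length(probs) == 3L, abs(sum(probs) - 1) < 1e-12)
  sp <- token_specials()
  nonpad <- which(!seq$pad)
  if (length(nonpad) == 0L) stop("sequence has no non-pad positions")
  n_sel <- max(1L, round(ratio * length(nonpad)))
  with_seed(child_seed(seed, "seq_mask"), {
    sel <- sort(sample(nonpad, n_sel))
    orig <- seq$tokens[sel]
    u <- stats::runif(n_sel)
    tokens <- seq$tokens
    aa_ids <- unname(sp$aa)
    for (i in seq_len(n_sel)) {
      p <- sel[i]
      if (u[i] < probs[1]) {
        tokens[p] <- sp$mask
      } else if (u[i] < probs[1] + probs[2]) {
        alt <- setdiff(aa_ids, orig[i])
        tokens[p] <- alt[sample.int(length(alt), 1L)]
      } # else keep
    }
    list(seq = tok_seq(tokens, seq$pad),
         targets = data.frame(position = sel, token = orig))
  })
}

#' Mask the point cloud around its centroid
#'
#' Computes the centroid of the real (non-pad) points and masks the
#' coordinates of the `round(fraction * n_real)` points nearest to it
#' (distance ties broken by lower index). Masked points receive sentinel
#' coordinates equal to the centroid of the points that remain visible, so
#' encoder inputs stay in-distribution; they are flagged via `coord_mask`
#' either way. Padding points are never candidates.
#'
#' @param c A `protein_cloud`.
#' @param fraction Fraction of real points to mask (default 0.25, i.e. 256
#'   of a 1024-point cloud).
#' @return List with `cloud` (corrupted) and `targets`, a data.frame of
#'   point `index` and true `x`, `y`, `z`.
#' @export
mask_pointcloud <- function(c, fraction = 0.25) {
  stopifnot(inherits(c, "protein_cloud"), fraction > 0, fraction < 1)
  real <- which(!c$pad & c$coord_mask)
  n_mask <- round(fraction * length(real))
  if (n_mask < 1L) n_mask <- 1L
  if (n_mask >= length(real))
    stop("cannot mask ", n_mask, " of ", length(real), " real points")
  ctr <- colMeans(c$coords[real, , drop = FALSE])
  d2 <- colSums((t(c$coords[real, , drop = FALSE]) - ctr)^2)
  ord <- order(d2, real)
  masked <- sort(real[ord][seq_len(n_mask)])
  targets <- data.frame(index = masked,
                        x = c$coords[masked, 1],
                        y = c$coords[masked, 2],
                        z = c$coords[masked, 3])
  out <- c
  out$coord_mask[masked] <- FALSE
  visible <- setdiff(real, masked)
  sentinel <- colMeans(c$coords[visible, , drop = FALSE])
  out$coords[masked, ] <- matrix(sentinel, n_mask, 3, byrow = TRUE)
  list(cloud = out, targets = targets)
}

#' Build one self-supervised training example
#'
#' Composes the full corruption pipeline: tokenize the sequence, align it
#' with the structure's point cloud, crop or pad to the context size, mask
#' the sequence and mask the point cloud. All child seeds derive from one
#' run seed, and sequence and point masking use independent streams.
#'
#' @param record A `protein_record`.
#' @param structure The matching `structure_model` (same residues).
#' @param config Named list; recognised keys `context_size` (default 1024),
#'   `mask_ratio` (0.15), `mask_probs` (0.8, 0.1, 0.1),
#'   `point_mask_fraction` (0.25), `crop_sampler` ("two-stage").
#' @param seed Integer run seed.
#' @return Object of class `training_example`: list with `seq` (corrupted),
#'   `cloud` (corrupted), `token_targets`, `coord_targets`, `window`,
#'   `seed`.
#' @export
make_training_example <- function(record, structure, config = list(),
                                  seed = 1) {
  stopifnot(inherits(record, "protein_record"),
            inherits(structure, "structure_model"))
  cfg <- utils::modifyList(list(context_size = 1024, mask_ratio = 0.15,
                                mask_probs = c(0.8, 0.1, 0.1),
                                point_mask_fraction = 0.25,
                                crop_sampler = "two-stage"), config)
  sseq <- structure_sequence(structure)
  rseq <- record$sequence
  if (nchar(sseq) != nchar(rseq)) {
    stop("sequence/structure length mismatch: ", nchar(rseq), " vs ",
         nchar(sseq))
  }
  rs <- strsplit(rseq, "")[[1]]; ss <- strsplit(sseq, "")[[1]]
  mism <- which(rs != ss & ss != "X" & rs != "X")
  if (length(mism) > 0L)
    stop("sequence/structure mismatch at position ", mism[1], ": '",
         rs[mism[1]], "' vs '", ss[mism[1]], "'")
  seq <- tokenize_sequence(rseq)
  cloud <- from_structure(structure)
  cp <- crop_or_pad(cloud, seq, context = cfg$context_size,
                    seed = child_seed(seed, "crop"),
                    sampler = cfg$crop_sampler)
  ms <- mask_sequence(cp$seq, ratio = cfg$mask_ratio, probs = cfg$mask_probs,
                      seed = child_seed(seed, "tokens"))
  mc <- mask_pointcloud(cp$cloud, fraction = cfg$point_mask_fraction)
  structure(list(seq = ms$seq, cloud = mc$cloud,
                 token_targets = ms$targets, coord_targets = mc$targets,
                 window = cp$window, seed = seed, config = cfg),
            class = "training_example")
}

#' @export
print.training_example <- function(x, ...) {
  cat(sprintf(paste0("<training_example> %d tokens (%d masked), ",
                     "%d points (%d coord-masked), window [%d, %d)\n"),
              length(x$seq$tokens), nrow(x$token_targets),
              length(x$cloud$P), nrow(x$coord_targets),
              x$window[1], x$window[2]))
  invisible(x)
}
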