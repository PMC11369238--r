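# Synthetic proteins with known ground truth: idealized secondary-structure
# C-alpha traces, geometry-coded sequences, additive fitness landscapes and
# fold-change tables, so every pipeline stage is testable offline.

.helix_coords <- function(n, rise = 1.5, radius = 2.3, turn_deg = 100) {
  i <- seq_len(n) - 1
  th <- i * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

.strand_coords <- function(n, rise = 3.3, pleat = 0.9) {
  i <- seq_len(n) - 1
  cbind(rise * i, pleat * (-1)^i, rep(0, n))
}

.random_sequence <- function(length, composition = NULL) {
  seq <- sample(AA_LETTERS, length, replace = TRUE)
  if (!is.null(composition)) {
    for (aa in names(composition)) {
      cnt <- composition[[aa]]
      if (cnt > length) stop("composition count for ", aa,
                             " exceeds length ", length)
      seq[seq == aa] <- sample(setdiff(AA_LETTERS, aa),
                               sum(seq == aa), replace = TRUE)
      seq[sample.int(length, cnt)] <- aa
    }
  }
  paste(seq, collapse = "")
}

.as_structure <- function(id, sequence, coords, confidence) {
  res <- data.frame(residue_index = seq_len(nrow(coords)),
                    residue_type = strsplit(sequence, "")[[1]],
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    confidence = confidence, stringsAsFactors = FALSE)
  structure(list(id = id, chain = "A", residues = res),
            class = "structure_model")
}

#' Ideal alpha-helix protein
#'
#' C-alpha trace of an ideal alpha helix (rise 1.5 A/residue, radius
#' 2.3 A, 100 degrees/residue; consecutive C-alpha spacing ~3.8 A) with
#' optional isotropic Gaussian coordinate noise. The sequence is drawn
#' uniformly over the 20 residues, subject to exact composition counts
#' (e.g. `composition = list(R = 36)` forces exactly 36 arginines).
#'
#' @param length Number of residues.
#' @param composition Named list of exact residue counts, or `NULL`.
#' @param sigma Coordinate noise standard deviation in Angstrom.
#' @param seed Integer seed.
#' @param confidence Per-residue confidence written into the structure
#'   (default 90, comfortably above the training-admission threshold).
#' @param id Record identifier.
#' @return List with `record` (`protein_record`) and `structure`
#'   (`structure_model`).
#' @export
make_helix <- function(length, composition = NULL, sigma = 0, seed = 1,
                       confidence = 90, id = "helix") {
  stopifnot(length >= 1, sigma >= 0)
  with_seed(child_seed(seed, "helix"), {
    sequence <- .random_sequence(length, composition)
    coords <- .helix_coords(length)
    if (sigma > 0) coords <- coords + matrix(stats::rnorm(3 * length,
                                                          sd = sigma),
                                             length, 3)
    list(record = protein_record(id, sequence),
         structure = .as_structure(id, sequence, coords, confidence))
  })
}

#' Ideal extended-strand protein
#'
#' Pleated extended trace (rise 3.3 A/residue); same conventions as
#' [make_helix()].
#'
#' @inheritParams make_helix
#' @export
make_strand <- function(length, composition = NULL, sigma = 0, seed = 1,
                        confidence = 90, id = "strand") {
  stopifnot(length >= 1, sigma >= 0)
  with_seed(child_seed(seed, "strand"), {
    sequence <- .random_sequence(length, composition)
    coords <- .strand_coords(length)
    if (sigma > 0) coords <- coords + matrix(stats::rnorm(3 * length,
                                                          sd = sigma),
                                             length, 3)
    list(record = protein_record(id, sequence),
         structure = .as_structure(id, sequence, coords, confidence))
  })
}

# residue coding rule: curvature class + position parity -> residue.
# helix (high local curvature) codes A/L, strand (extended) codes V/T.
.geometry_code <- function(classes, positions) {
  ifelse(classes == "helix",
         ifelse(positions %% 2 == 0, "A", "L"),
         ifelse(positions %% 2 == 0, "V", "T"))
}

#' Geometry-coded synthetic proteins
#'
#' Proteins built from alternating helix and strand segments in which the
#' residue identity is a deterministic function of the local backbone
#' geometry class and position parity (helix residues are A/L, strand
#' residues V/T). Masked-token recovery above chance is therefore
#' achievable from structure context alone, which is the learnable signal
#' used to validate the training loop. Shuffling the coordinates destroys
#' the geometric half of the signal.
#'
#' @param n Number of proteins.
#' @param length Residues per protein.
#' @param sigma Coordinate noise (Angstrom, default 0.2).
#' @param seed Integer seed.
#' @return List of `n` elements, each with `record`, `structure` and the
#'   per-residue `classes` vector.
#' @export
make_geometry_coded_set <- function(n, length = 48, sigma = 0.2, seed = 1) {
  stopifnot(n >= 1, length >= 8)
  lapply(seq_len(n), function(i) {
    with_seed(child_seed(seed, paste0("geo", i)), {
      classes <- character(0)
      coords <- matrix(0, 0, 3)
      cls <- sample(c("helix", "strand"), 1)
      origin <- c(0, 0, 0)
      while (nrow(coords) < length) {
        seg_len <- min(sample(8:16, 1), length - nrow(coords))
        seg <- if (cls == "helix") .helix_coords(seg_len)
               else .strand_coords(seg_len)
        # random orientation, attached near the previous segment end
        Rt <- random_rigid_transform(sample.int(2^30, 1), scale = 0)$rotation
        seg <- seg %*% t(Rt)
        seg <- sweep(seg, 2, origin - seg[1, ] +
                       c(stats::rnorm(3, sd = 2)), `+`)
        coords <- rbind(coords, seg)
        classes <- c(classes, rep(cls, seg_len))
        origin <- coords[nrow(coords), ] + c(4, 0, 0)
        cls <- if (cls == "helix") "strand" else "helix"
      }
      if (sigma > 0)
        coords <- coords + matrix(stats::rnorm(3 * length, sd = sigma),
                                  length, 3)
      sequence <- paste(.geometry_code(classes, seq_len(length)),
                        collapse = "")
      id <- sprintf("geo%03d", i)
      list(record = protein_record(id, sequence),
           structure = .as_structure(id, sequence, coords, 90),
           classes = classes)
    })
  })
}

#' Additive synthetic fitness landscape
#'
#' Per-position, per-residue true fitness contributions with the wild-type
#' contribution fixed at 0 everywhere, matching the scorer's WT = 0
#' identity exactly.
#'
#' @param reference A `protein_record`.
#' @param sd Contribution standard deviation (default 1).
#' @param seed Integer seed.
#' @return L x 20 matrix (columns in [AA_LETTERS] order) of class
#'   `synthetic_landscape`, reference attached.
#' @export
make_landscape <- function(reference, sd = 1, seed = 1) {
  L <- reference$L
  ref <- strsplit(reference$sequence, "")[[1]]
  with_seed(child_seed(seed, "landscape"), {
    M <- matrix(stats::rnorm(L * 20, sd = sd), L, 20,
                dimnames = list(NULL, AA_LETTERS))
    M[cbind(seq_len(L), match(ref, AA_LETTERS))] <- 0
    attr(M, "reference") <- reference$sequence
    class(M) <- c("synthetic_landscape", class(M))
    M
  })
}

#' Log-probability table realizing a landscape
#'
#' Builds a `logit_table` whose per-position log-probability differences
#' reproduce the landscape contributions exactly (softmax of contributions
#' per position; special tokens get negligible mass), optionally perturbed
#' by Gaussian logit noise. With zero noise, [score_variant()] on this
#' table recovers the true additive fitness of every variant exactly.
#'
#' @param landscape A `synthetic_landscape`.
#' @param noise_sd Logit noise standard deviation (default 0).
#' @param seed Integer seed for the noise.
#' @return A `logit_table`.
#' @export
make_landscape_table <- function(landscape, noise_sd = 0, seed = 1) {
  L <- nrow(landscape)
  ids <- .token_ids()
  logits <- matrix(-30, L, 33)
  logits[, unname(ids[AA_LETTERS])] <- unclass(landscape)
  if (noise_sd > 0)
    logits <- logits + with_seed(child_seed(seed, "tabnoise"),
                                 matrix(stats::rnorm(L * 33, sd = noise_sd),
                                        L, 33))
  mx <- apply(logits, 1, max)
  lp <- logits - (mx + log(rowSums(exp(logits - mx))))
  rownames(lp) <- as.character(seq_len(L))
  attr(lp, "reference") <- attr(landscape, "reference")
  class(lp) <- c("logit_table", class(lp))
  lp
}

#' Labeled fold-change dataset from a landscape
#'
#' Samples single variants (half biased to beneficial, half to deleterious
#' contributions so both classes are populated), generates fold changes as
#' `exp(true score) * exp(noise)` with lognormal noise, and labels them via
#' [label_fold_change()]. Zero-noise labels are perfectly separable by the
#' true score.
#'
#' @param landscape A `synthetic_landscape`.
#' @param n Number of variants (>= 4).
#' @param noise_sd Lognormal noise sigma (default 0).
#' @param seed Integer seed.
#' @return Data.frame with `variant`, `true_score`, `fold_change`, `label`.
#' @export
make_fold_change_dataset <- function(landscape, n = 27, noise_sd = 0,
                                     seed = 1) {
  stopifnot(n >= 4)
  ref <- strsplit(attr(landscape, "reference"), "")[[1]]
  L <- length(ref)
  all <- expand.grid(position = seq_len(L), mt = AA_LETTERS,
                     stringsAsFactors = FALSE)
  all$wt <- ref[all$position]
  all <- all[all$wt != all$mt, ]
  all$score <- unclass(landscape)[cbind(all$position,
                                        match(all$mt, AA_LETTERS))]
  with_seed(child_seed(seed, "foldchange"), {
    pos_pool <- all[all$score > 0.25, ]
    neg_pool <- all[all$score < -0.25, ]
    n_pos <- ceiling(n / 2)
    take <- function(pool, k) pool[sample.int(nrow(pool), k), ]
    chosen <- rbind(take(pos_pool, min(n_pos, nrow(pos_pool))),
                    take(neg_pool, n - min(n_pos, nrow(pos_pool))))
    noise <- if (noise_sd > 0) exp(stats::rnorm(n, sd = noise_sd)) else 1
    fc <- exp(chosen$score) * noise
    data.frame(variant = sprintf("%s%d%s", chosen$wt, chosen$position,
                                 chosen$mt),
               true_score = chosen$score, fold_change = fc,
               label = label_fold_change(fc), stringsAsFactors = FALSE)
  })
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' One ATOM record per residue (CA only), with the confidence in the
#' B-factor column, so synthetic fixtures flow through the real structure
#' reader.
#'
#' @param s A `structure_model`.
#' @param path Output path.
#' @export
write_ca_pdb <- function(s, path) {
  aa13 <- names(.aa321)[match(s$residues$residue_type,
                              .aa321[seq_len(20)])]
  aa13[is.na(aa13)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    s$residues$residue_index, aa13, s$chain, s$residues$residue_index,
    s$residues$x, s$residues$y, s$residues$z, 1.00,
    s$residues$confidence)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
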