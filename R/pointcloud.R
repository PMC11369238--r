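#' Protein point cloud
#'
#' An ordered set of per-residue points, one per C-alpha atom. Each point
#' carries `[x, y, z, R, P]`: coordinates in Angstrom, the residue type `R`
#' and the 1-based sequence position `P`. `coord_mask` marks points whose
#' coordinates are observed (`FALSE` = masked for point completion), `pad`
#' marks synthetic padding points appended by [crop_or_pad()].
#'
#' @param coords Numeric n x 3 matrix of coordinates (Angstrom).
#' @param R Character vector of residue one-letter codes.
#' @param P Integer vector of 1-based sequence positions.
#' @param coord_mask Logical vector; `TRUE` where coordinates are observed.
#' @param pad Logical vector of padding flags.
#' @return Object of class `protein_cloud`.
#' @export
protein_cloud <- function(coords, R, P = seq_len(nrow(coords)),
                          coord_mask = rep(TRUE, nrow(coords)),
                          pad = rep(FALSE, nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3L, length(R) == n, length(P) == n,
            length(coord_mask) == n, length(pad) == n)
  P <- as.integer(P)
  if (any(diff(P[!pad]) <= 0))
    stop("P values must be strictly increasing over non-pad points")
  if (any(!is.finite(coords[coord_mask, , drop = FALSE])))
    stop("observed coordinates must be finite")
  structure(list(coords = coords, R = as.character(R), P = P,
                 coord_mask = as.logical(coord_mask), pad = as.logical(pad)),
            class = "protein_cloud")
}

#' @export
print.protein_cloud <- function(x, ...) {
  cat(sprintf("<protein_cloud> %d points (%d masked, %d pad)\n",
              length(x$P), sum(!x$coord_mask), sum(x$pad)))
  invisible(x)
}

#' @export
length.protein_cloud <- function(x) length(x$P)

#' Build a point cloud from a structure model
#'
#' One point per residue in chain order; `R` copies the residue type, `P`
#' the internal 1..L numbering, and all coordinates are observed.
#'
#' @param s A `structure_model` from [read_structure()].
#' @return A `protein_cloud`.
#' @export
from_structure <- function(s) {
  stopifnot(inherits(s, "structure_model"), nrow(s$residues) >= 1L)
  protein_cloud(as.matrix(s$residues[, c("x", "y", "z")]),
                R = s$residues$residue_type,
                P = s$residues$residue_index)
}

#' Centroid of the observed points
#'
#' Arithmetic mean of the coordinates with `coord_mask` true (padding points
#' included only if observed, which padded resampled points are; callers that
#' need real points only should subset first).
#'
#' @param c A `protein_cloud`.
#' @param real_only If `TRUE` (default), padding points are excluded.
#' @return Numeric 3-vector.
#' @export
centroid <- function(c, real_only = TRUE) {
  keep <- c$coord_mask & (!real_only | !c$pad)
  if (!any(keep)) stop("no observed points: centroid undefined")
  colMeans(c$coords[keep, , drop = FALSE])
}

#' k-nearest neighbourhoods of each point
#'
#' For every point, the indices of the `min(k, n_obs - 1)` nearest other
#' observed points by Euclidean distance, self excluded. Distance ties are
#' broken by lower point index so results are deterministic. Masked and pad
#' points are never neighbours, but each still receives a (possibly empty)
#' neighbour list computed from its own coordinates.
#'
#' @param c A `protein_cloud`.
#' @param k Number of neighbours (default 30, the structure-context size).
#' @return List of integer index vectors, one per point, each ordered by
#'   increasing distance.
#' @export
knn_neighborhoods <- function(c, k = 30) {
  stopifnot(k >= 1)
  n <- length(c$P)
  obs <- which(c$coord_mask & !c$pad)
  out <- vector("list", n)
  if (length(obs) == 0L) return(lapply(out, function(x) integer(0)))
  X <- c$coords
  for (i in seq_len(n)) {
    cand <- setdiff(obs, i)
    if (length(cand) == 0L || !all(is.finite(X[i, ]))) {
      out[[i]] <- integer(0)
      next
    }
    d2 <- colSums((t(X[cand, , drop = FALSE]) - X[i, ])^2)
    ord <- order(d2, cand)   # ties by lower index
    out[[i]] <- cand[ord][seq_len(min(k, length(cand)))]
  }
  out
}

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector (Angstrom).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Draw a random rigid transform
#'
#' Rotation sampled uniformly (QR of a Gaussian matrix, sign-fixed to
#' det +1), translation components uniform on `[-scale, scale]`.
#'
#' @param seed Integer seed.
#' @param scale Translation half-range in Angstrom (default 50).
#' @export
random_rigid_transform <- function(seed, scale = 50) {
  with_seed(seed, {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    rigid_transform(Q, stats::runif(3, -scale, scale))
  })
}

#' Apply a rigid transform to a point cloud
#'
#' Coordinates become `R x + t`; residue types, positions, masks and pad
#' flags are unchanged.
#'
#' @param c A `protein_cloud`.
#' @param t A `rigid_transform`.
#' @export
apply_transform <- function(c, t) {
  stopifnot(inherits(t, "rigid_transform"))
  out <- c
  out$coords <- sweep(c$coords %*% t(t$rotation), 2, t$translation, `+`)
  out
}

#' Symmetric Chamfer distance between two point sets
#'
#' `0.5 * (mean_a min_b ||a-b||^2 + mean_b min_a ||b-a||^2)`: the average
#' nearest squared distance in both directions, symmetrized. Permutation
#' invariant and zero iff the point multisets coincide.
#'
#' @param a,b Numeric n x 3 matrices (or `protein_cloud`s, in which case the
#'   observed non-pad points are used).
#' @return Non-negative scalar (Angstrom squared).
#' @export
chamfer_distance <- function(a, b) {
  a <- .as_points(a); b <- .as_points(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("chamfer_distance requires non-empty point sets")
  d2 <- .cross_dist2(a, b)
  0.5 * (mean(apply(d2, 1, min)) + mean(apply(d2, 2, min)))
}

.as_points <- function(x) {
  if (inherits(x, "protein_cloud")) {
    keep <- x$coord_mask & !x$pad
    x <- x$coords[keep, , drop = FALSE]
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# pairwise squared distances, n x m
.cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Crop or pad a cloud + sequence pair to the model context
#'
#' Proteins longer than `context` are cropped with a two-stage integer
#' sampler: with `n = L - context`, first `x ~ Uniform{0..n}`, then
#' `start ~ Uniform{1..n-x+1}` and the window is `[start, start+context)`.
#' Proteins shorter than `context` are right-padded: pad tokens on the
#' sequence, and padding points resampled uniformly with replacement from
#' the real points on the cloud (padded entries are flagged and excluded
#' from every loss). A single-uniform sampler (`start ~ Uniform{1..n+1}`)
#' is available via `sampler = "single"`.
#'
#' @param c A `protein_cloud` of length L.
#' @param seq A `tok_seq` of the same length.
#' @param context Target length (default 1024).
#' @param seed Integer seed for the sampler.
#' @param sampler `"two-stage"` (default) or `"single"`.
#' @return List with `cloud`, `seq` (both of length `context`) and `window`,
#'   the 1-based `[start, end)` window into the original protein.
#' @export
crop_or_pad <- function(c, seq, context = 1024, seed = 1,
                        sampler = c("two-stage", "single")) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(c, "protein_cloud"), inherits(seq, "tok_seq"))
  if (context < 1) stop("context must be >= 1")
  L <- length(c$P)
  if (L != length(seq$tokens)) stop("cloud and sequence lengths differ")
  sp <- token_specials()
  if (L >= context) {
    start <- if (L == context) 1L else with_seed(seed, {
      n <- L - context
      if (sampler == "two-stage") {
        x <- sample.int(n + 1L, 1L) - 1L          # x in {0..n}
        sample.int(n - x + 1L, 1L)                # start in {1..n-x+1}
      } else sample.int(n + 1L, 1L)
    })
    idx <- start:(start + context - 1L)
    cloud <- protein_cloud(c$coords[idx, , drop = FALSE], c$R[idx], c$P[idx],
                           c$coord_mask[idx], c$pad[idx])
    sq <- tok_seq(seq$tokens[idx], seq$pad[idx])
    return(list(cloud = cloud, seq = sq,
                window = as.integer(c(start, start + context))))
  }
  n_pad <- context - L
  pad_idx <- with_seed(child_seed(seed, "cloud_pad"),
                       sample.int(L, n_pad, replace = TRUE))
  coords <- rbind(c$coords, c$coords[pad_idx, , drop = FALSE])
  R <- c(c$R, c$R[pad_idx])
  P <- c(c$P, c$P[pad_idx])
  cm <- c(c$coord_mask, c$coord_mask[pad_idx])
  pd <- c(c$pad, rep(TRUE, n_pad))
  cloud <- structure(list(coords = coords, R = R, P = as.integer(P),
                          coord_mask = cm, pad = pd),
                     class = "protein_cloud")
  sq <- tok_seq(c(seq$tokens, rep(sp$pad, n_pad)),
                c(seq$pad, rep(TRUE, n_pad)))
  list(cloud = cloud, seq = sq, window = c(1L, L + 1L))
}

#' Serialize a point cloud to TSV
#' @param c A `protein_cloud`.
#' @param path Output path.
#' @export
write_cloud_tsv <- function(c, path) {
  df <- data.frame(x = c$coords[, 1], y = c$coords[, 2], z = c$coords[, 3],
                   R = c$R, P = c$P, mask = as.integer(!c$coord_mask),
                   pad = as.integer(c$pad))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a point cloud from TSV written by [write_cloud_tsv()]
#' @param path Input path.
#' @export
read_cloud_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  protein_cloud(as.matrix(df[, c("x", "y", "z")]), df$R, df$P,
                coord_mask = df$mask == 0, pad = df$pad == 1)
}

# Canonical frame of a set of observed points: centroid at the origin, axes
# the covariance eigenvectors ordered by decreasing eigenvalue, signs fixed
# by the third central moment along each axis (falling back to an index-
# weighted first moment when that vanishes), third axis by cross product so
# det = +1. Equivariant under proper rigid motions, which makes decoded
# coordinates mapped back through it equivariant too.
canonical_frame <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) return(list(Q = diag(3), c = if (n > 0) colMeans(X) else c(0, 0, 0)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(crossprod(Xc) / n, symmetric = TRUE)
  axes <- matrix(0, 3, 2)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    s <- sum((Xc %*% v)^3)
    if (abs(s) < 1e-9) s <- sum((Xc %*% v) * seq_len(n))
    if (s < 0) v <- -v
    axes[, j] <- v
  }
  v3 <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
          axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
          axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  list(Q = cbind(axes, v3), c = ctr)
}
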