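test_that("cloud construction mirrors the structure", {
  s <- read_structure(toy_pdb())
  cl <- from_structure(s)
  expect_equal(cl$P, 1:3)
  expect_equal(cl$R, c("G", "A", "V"))
  expect_equal(length(cl), nrow(s$residues))
  expect_true(all(cl$coord_mask))
})

test_that("centroid is the mean of observed points and is linear", {
  cl <- protein_cloud(rbind(c(0, 0, 0), c(2, 0, 0)), c("A", "G"))
  expect_equal(centroid(cl), c(1, 0, 0))
  one <- protein_cloud(matrix(c(3, -1, 2), 1), "A")
  expect_equal(centroid(one), c(3, -1, 2))
  t <- rigid_transform(diag(3), c(5, -2, 1))
  expect_equal(centroid(apply_transform(cl, t)), c(6, -2, 1))
  masked <- protein_cloud(matrix(0, 2, 3), c("A", "G"),
                          coord_mask = c(FALSE, FALSE))
  expect_error(centroid(masked), "no observed")
})

test_that("kNN neighbourhoods match the brute-force oracle with tie rule", {
  # collinear points: middle point's distance ties break to lower index
  cl <- protein_cloud(cbind(c(0, 1, 2), 0, 0), c("A", "G", "V"))
  nb <- knn_neighborhoods(cl, k = 1)
  expect_equal(nb[[2]], 1L)
  # n = 5, k larger than n-1: everyone gets 4 neighbours
  set.seed(3)
  X <- matrix(rnorm(15), 5, 3)
  cl5 <- protein_cloud(X, rep("A", 5))
  nb5 <- knn_neighborhoods(cl5, k = 30)
  expect_true(all(lengths(nb5) == 4L))
  expect_equal(nb5, knn_oracle(X, 30))
  # random clouds vs oracle at several k
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(36), 12, 3)
    cl12 <- protein_cloud(X, rep("A", 12))
    for (k in c(1, 4, 11))
      expect_equal(knn_neighborhoods(cl12, k), knn_oracle(X, k))
  }
})

test_that("kNN is invariant under rigid transforms", {
  inp <- helix_inputs(30, sigma = 0.4, seed = 8)
  nb <- knn_neighborhoods(inp$cloud, k = 5)
  for (seed in 1:5) {
    t <- random_rigid_transform(seed)
    expect_identical(knn_neighborhoods(apply_transform(inp$cloud, t), k = 5),
                     nb)
  }
})

test_that("rigid transforms preserve pairwise distances and validate input", {
  inp <- helix_inputs(25, sigma = 0.2, seed = 2)
  t <- random_rigid_transform(11)
  d0 <- dist(inp$cloud$coords)
  d1 <- dist(apply_transform(inp$cloud, t)$coords)
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "det")
  idc <- apply_transform(inp$cloud, rigid_transform())
  expect_equal(idc$coords, inp$cloud$coords)
})

test_that("crop window rules: exact fit, long proteins, short proteins", {
  inp <- helix_inputs(64, sigma = 0, seed = 4)
  cp <- crop_or_pad(inp$cloud, inp$seq, context = 64, seed = 1)
  expect_equal(cp$window, c(1L, 65L))
  expect_false(any(cp$seq$pad))

  # L = context + 1: both start positions reachable across seeds
  inp2 <- helix_inputs(65, sigma = 0, seed = 4)
  starts <- vapply(1:40, function(s)
    crop_or_pad(inp2$cloud, inp2$seq, context = 64, seed = s)$window[1], 1L)
  expect_setequal(unique(starts), c(1L, 2L))

  # short protein: padding flagged, count exact
  inp3 <- helix_inputs(10, sigma = 0, seed = 4)
  cp3 <- crop_or_pad(inp3$cloud, inp3$seq, context = 64, seed = 2)
  expect_equal(sum(cp3$seq$pad), 54L)
  expect_equal(sum(cp3$cloud$pad), 54L)
  expect_equal(length(cp3$cloud), 64L)
  sp <- token_specials()
  expect_true(all(cp3$seq$tokens[cp3$seq$pad] == sp$pad))
  # padded cloud points are resampled real points
  pad_coords <- cp3$cloud$coords[cp3$cloud$pad, , drop = FALSE]
  real_coords <- inp3$cloud$coords
  expect_true(all(apply(pad_coords, 1, function(p)
    any(colSums(abs(t(real_coords) - p)) < 1e-12))))
  expect_error(crop_or_pad(inp3$cloud, inp3$seq, context = 0), "context")
})

test_that("crop windows always lie inside the protein", {
  for (seed in 1:20) {
    inp <- helix_inputs(90, sigma = 0, seed = 1)
    cp <- crop_or_pad(inp$cloud, inp$seq, context = 64, seed = seed)
    expect_gte(cp$window[1], 1L)
    expect_lte(cp$window[2] - 1L, 90L)
    expect_equal(cp$window[2] - cp$window[1], 64L)
  }
})

test_that("Chamfer distance: identities, singleton case, oracle agreement", {
  set.seed(9)
  A <- matrix(rnorm(18), 6, 3)
  expect_equal(chamfer_distance(A, A), 0)
  expect_equal(chamfer_distance(A, A[sample(6), ]), 0)  # permutation
  expect_equal(chamfer_distance(matrix(c(0, 0, 0), 1),
                                matrix(c(3, 0, 0), 1)), 9.0)
  for (seed in 1:10) {
    set.seed(seed)
    A <- matrix(rnorm(18, sd = 3), 6, 3)
    B <- matrix(rnorm(24, sd = 3), 8, 3)
    expect_lt(abs(chamfer_distance(A, B) - chamfer_oracle(A, B)), 1e-9)
    expect_equal(chamfer_distance(A, B), chamfer_distance(B, A))
  }
  expect_error(chamfer_distance(A[0, , drop = FALSE], A), "non-empty")
})

test_that("Chamfer distance is invariant under a joint rigid transform", {
  set.seed(12)
  A <- matrix(rnorm(21), 7, 3)
  B <- matrix(rnorm(15), 5, 3)
  base <- chamfer_distance(A, B)
  for (seed in 1:5) {
    t <- random_rigid_transform(seed)
    A2 <- sweep(A %*% t(t$rotation), 2, t$translation, `+`)
    B2 <- sweep(B %*% t(t$rotation), 2, t$translation, `+`)
    expect_lt(abs(chamfer_distance(A2, B2) - base), 1e-9)
  }
})

test_that("cloud TSV serialization round-trips", {
  inp <- helix_inputs(15, sigma = 0.1, seed = 6)
  f <- tempfile(fileext = ".tsv")
  write_cloud_tsv(inp$cloud, f)
  back <- read_cloud_tsv(f)
  expect_equal(back$coords, inp$cloud$coords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$R, inp$cloud$R)
  expect_equal(back$P, inp$cloud$P)
})
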