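# Fixtures are built in code at test time; no binary data on disk.

# hand-written 3-residue PDB (Gly-Ala-Val CA trace on the x axis) so the
# reader is tested against text independent of the package's own writer
toy_pdb <- function(path = tempfile(fileext = ".pdb"), chain = "A",
                    bfac = c(90, 90, 90)) {
  lines <- c(
    sprintf("ATOM      1  CA  GLY %s   1       0.000   0.000   0.000  1.00 %5.2f           C", chain, bfac[1]),
    sprintf("ATOM      2  CA  ALA %s   2       3.800   0.000   0.000  1.00 %5.2f           C", chain, bfac[2]),
    sprintf("ATOM      3  CA  VAL %s   3       7.600   0.000   0.000  1.00 %5.2f           C", chain, bfac[3]),
    "END")
  writeLines(lines, path)
  path
}

two_chain_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 80.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00 80.00           C",
    "ATOM      3  CA  LEU B   1       0.000   5.000   0.000  1.00 70.00           C",
    "ATOM      4  CA  LYS B   2       3.800   5.000   0.000  1.00 70.00           C",
    "ATOM      5  CA  SER B   3       7.600   5.000   0.000  1.00 70.00           C",
    "END")
  writeLines(lines, path)
  path
}

# residue 2 has no CA (only N) -> must be dropped with a warning
missing_ca_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 90.00           C",
    "ATOM      2  N   ALA A   2       3.800   0.000   0.000  1.00 90.00           N",
    "ATOM      3  CA  VAL A   3       7.600   0.000   0.000  1.00 90.00           C",
    "END")
  writeLines(lines, path)
  path
}

# O(n^2) brute-force Chamfer oracle, independent of the implementation
chamfer_oracle <- function(A, B) {
  d2 <- function(p, q) sum((p - q)^2)
  fwd <- mean(apply(A, 1, function(p) min(apply(B, 1, d2, p = p))))
  bwd <- mean(apply(B, 1, function(q) min(apply(A, 1, d2, p = q))))
  (fwd + bwd) / 2
}

# brute-force kNN oracle (full sort of all pairwise distances)
knn_oracle <- function(coords, k, obs = seq_len(nrow(coords))) {
  lapply(seq_len(nrow(coords)), function(i) {
    cand <- setdiff(obs, i)
    d <- sqrt(colSums((t(coords[cand, , drop = FALSE]) - coords[i, ])^2))
    ord <- order(d, cand)
    cand[ord][seq_len(min(k, length(cand)))]
  })
}

small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- model_config(K = 32, encoder_layers = 2, encoder_heads = 4,
                          context = 64, knn = 10, struct_heads = 4)
      cache <<- init_model(cfg, seed = 42)
    }
    cache
  }
})

# cloud + sequence pair from a noisy helix, aligned
helix_inputs <- function(length = 40, sigma = 0.3, seed = 5) {
  h <- make_helix(length, sigma = sigma, seed = seed)
  list(seq = tokenize_sequence(h$record$sequence),
       cloud = from_structure(h$structure),
       record = h$record, structure = h$structure)
}

# a 408-residue reference with exactly 36 arginines and fixed wild-type
# letters at the positions of the seven-entry banned list
tnpb_like_record <- function() {
  set.seed(408)
  seq <- sample(setdiff(AA_LETTERS, "R"), 408, replace = TRUE)
  seq[sample(setdiff(seq_len(408), c(388, 217, 398, 405, 406, 44, 403)),
             36)] <- "R"
  seq[388] <- "Y"; seq[217] <- "S"; seq[398] <- "L"; seq[405] <- "T"
  seq[406] <- "L"; seq[44] <- "K"; seq[403] <- "H"
  protein_record("tnpb_like", paste(seq, collapse = ""))
}

banned_seven <- c("Y388R", "S217R", "L398R", "T405R", "L406R", "K44R",
                  "H403R")
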