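---
title: "Multimodal masked protein modelling and mutation-effect scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal masked protein modelling and mutation-effect scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutpoint)
```

## The model

`mutpoint` couples two views of a protein. The *sequence view* is the amino-acid
string tokenized over a fixed 33-symbol vocabulary (four leading specials, the
20 canonical residues, rare/ambiguity codes, alignment symbols, a reserved null
and a trailing mask token, in the ESM1b-style order). The *structure view* is a
protein point cloud: one point `[x, y, z, R, P]` per residue, anchored at its
Cα atom, carrying the residue type `R` and the 1-based position `P`. Both views
are embedded to width `K`, fused position-wise (element-wise sum by default),
passed through a stack of pre-LayerNorm transformer encoder blocks, and decoded
by two heads:

* a **sequence decoder** (linear → GELU → LayerNorm → linear → log-softmax)
  emitting an `L × 33` matrix of per-position token log-probabilities, and
* a **structure decoder** (three-layer ReLU MLP) emitting `L × 3` recovered
  Cα coordinates.

Training is self-supervised completion of corrupted inputs: 15% of non-pad
tokens are selected (exactly `round(0.15·n)`, at least one), each replaced by
the mask token with probability 0.8, by a uniformly chosen *different*
canonical residue with 0.1, or kept with 0.1; and the `round(0.25·n)` points
nearest the protein centroid have their coordinates masked. The loss is the
unweighted sum of a categorical cross-entropy over masked tokens and a
symmetric Chamfer distance between the decoded and true coordinates of the
masked points. Optimization is Adam (β = 0.9/0.999) with a linear warm-up to
the base learning rate followed by inverse-square-root decay, and gradient
clipping at global norm 1.

The entire network — forward pass, analytic backpropagation and the optimizer —
is implemented in base R matrix algebra. That makes the implementation small
enough to audit line by line and testable against finite differences (the test
suite checks analytic gradients of every parameter group against central
differences on a tiny configuration).

## The SE(3) contract and how it is met

The biological content of a structure is unchanged by rigid motion, so the
token log-probabilities, residue representations and pooled representation must
be invariant to any proper rotation plus translation of the input coordinates,
while decoded coordinates must co-transform (equivariance). Two design choices
deliver this exactly rather than approximately:

1. **Invariant structure features.** Each observed point is described by the
   sorted distances to its `knn` nearest observed neighbours (two channels per
   neighbour, `exp(−d/4)` and `d/10`, zero-padded), which are exactly invariant
   under isometry. A linear projection and one 8-head attention block (keys
   restricted to observed points) turn these into per-point structure
   embeddings. No absolute coordinate ever enters the encoder.
2. **Canonical-frame decoding.** The structure decoder predicts coordinates in
   a canonical frame of the observed points — centroid at the origin, axes the
   covariance eigenvectors ordered by decreasing eigenvalue, the sign of each
   axis fixed by the third central moment along it (with an index-weighted
   first moment as a tie-break when that vanishes), and the third axis formed
   by the cross product so the frame is a proper rotation. Predictions are
   mapped back through the inverse frame. Because the frame co-rotates with
   the input, the mapped predictions are equivariant.

The contract is tested numerically: over 100 random rigid transforms the
maximum log-probability deviation must stay below 1e-4 and the coordinate
equivariance deviation below 1e-3 Å; in practice both sit at machine precision
(~1e-14). The canonical frame degrades only when the covariance eigenvalues are
degenerate (e.g. perfectly symmetric point sets); the noisy, generic clouds the
package works with keep the eigenvalue gaps well away from zero.

A coordinate-masked point carries no geometry, so its structure embedding is a
learned null vector; it still *attends to* observed points in the structure
branch, which is what makes point completion learnable. A cloud with no
observed points at all (sequence-only degenerate mode) runs on the null
embedding everywhere and still returns valid log-probabilities.

## Scoring variants

Fitness scoring is *WT-marginal*: the intact wild-type sequence and structure
are fed through the model once, giving an `L × 33` table of log-probabilities,
and a variant with substitutions at positions `T` scores
`Σ_{t∈T} [log p(mt) − log p(wt)]` read from that table. The wild type scores
exactly 0, a reverted substitution scores the exact negative of the forward
one, and multi-site variants are additive in their constituents — which is
what lets an 8.5-million-member combinatorial library be ranked from one
forward pass by pure arithmetic. A *masked-marginal* mode (mask position `t`,
one forward pass per position, read row `t`) is available via
`logit_table(..., mode = "masked")` for users who prefer the conditional
reading of the probabilities; it costs `L` forward passes.

Pathogenicity of a single substitution `w→m` at position `i` is
`sigmoid(logit_i^w − logit_i^m − τ)` with the handcrafted offset `τ = 6` and a
*strict* classification threshold of 0.5 (a gap of exactly `τ` is therefore
benign). `τ = 0` reproduces the alternative convention used by some baseline
scorers. Because both logits are read from the same softmax row, the
normalizer cancels and log-probabilities can be used directly.

Supervised fine-tuning on experimental fold changes labels a variant positive
when its fold change exceeds 1.2 and negative below 0.8 — both strict, so the
closed interval `[0.8, 1.2]` is excluded — splits the labelled set
`round(0.8·n)` / remainder with a seeded shuffle, and minimizes the binary
cross-entropy of `sigmoid(Σ_t (logit_mt − logit_wt))`. A multi-site variant
sums (not averages) over its substitutions, consistent with the fitness score.

## Tunable parameters

| Parameter | Default (desk) | Reference scale | Meaning |
|---|---|---|---|
| `K` | 64 | 1280 | embedding width |
| `encoder_layers × heads` | 2 × 4 | 33 × 20 | transformer encoder |
| `context` | 128 | 1024 | maximum sequence/cloud length |
| `struct_layers × heads` | 1 × 8 | 1 × 8 | structure-branch attention |
| `knn` | 30 | 30 | structure-context neighbourhood size |
| `mask_ratio` | 0.15 | 0.15 | fraction of tokens corrupted |
| `mask_probs` | 0.8/0.1/0.1 | same | mask / random / keep split |
| `point_mask_fraction` | 0.25 | 0.25 (256 of 1024) | fraction of points masked |
| `base_lr`, `warmup_steps` | 1e-4, 10000 | same | Adam schedule |
| `tau` | 6 | 6 | pathogenicity offset |

The desk defaults are the test configuration: large enough to exhibit every
behaviour of the architecture, small enough that the full suite (including a
training run) completes in minutes on one CPU. The reference-scale
configuration is constructible (`model_config(K = 1280, encoder_layers = 33,
encoder_heads = 20, context = 1024)`) but nothing in the package requires it.

Proteins longer than the context are cropped with a deliberately literal
two-stage integer sampler: with `n = L − context`, draw `x ~ Uniform{0..n}`
and then `start ~ Uniform{1..n−x+1}`. The two-stage form is unusual (it biases
starts towards the N-terminus relative to a single uniform draw), and a
single-uniform alternative is exposed via `crop_or_pad(..., sampler =
"single")`; the two-stage recipe remains the default. Shorter proteins are
right-padded — pad tokens on the sequence, points resampled uniformly with
replacement from the real points on the cloud — with padded entries flagged
and excluded from attention normalization, losses, masking candidacy and
pooled representations.

## Numerical choices and tie-breaks

* **Chamfer symmetrization**: the average nearest squared distance is computed
  in both directions and the two means averaged; this is the
  permutation-invariant form of the point-completion literature, zero exactly
  when the multisets coincide.
* **kNN ties** break to the lower point index; **ranking ties** everywhere
  (score tables, extreme selection) break by variant-string lexicographic
  order. Both choices exist purely for reproducibility.
* **Masked-point sentinels** are the centroid of the still-visible points
  rather than zeros, keeping encoder inputs in-distribution; the
  `coord_mask` flag is authoritative either way.
* **Initialization** draws every weight from N(0, 0.02²) (layer norms at
  identity), which makes a fresh model's per-position token distributions
  near-uniform — the suite checks mean entropy ≥ 0.9·ln 33 at init, so
  scoring tables from untrained models are noise, not structure.
* **Masking counts** use `round()` with a floor of one selection, so even
  very short sequences produce a training signal.
* **Cross-entropy** is computed over masked positions only (the BERT
  convention); the Chamfer loss over masked points only (the completion
  targets), not the full cloud — the alternative (full-cloud) reading is
  noted but not implemented.
* The streamed combinatorial enumerator yields chunks sharing a prefix of
  `k−1` positions with the last position vectorized; top/bottom selection
  keeps bounded buffers pruned by partial sort, and the test suite checks the
  streamed selection against a full sort on a small library.

## What the synthetic data emulates — and what it does not

The generators stand in for predicted-structure databases and deep
mutational-scanning tables:

* `make_helix()` / `make_strand()` produce ideal secondary-structure Cα
  traces (helix rise 1.5 Å/residue, radius 2.3 Å, 100°/residue — consecutive
  Cα spacing ≈ 3.8 Å) with optional Gaussian coordinate noise and exact
  residue-composition constraints (e.g. a 408-residue reference with exactly
  36 arginines, so its triple X-to-R library has exactly
  `C(372,3) = 8,510,740` members).
* `make_geometry_coded_set()` builds proteins from alternating helix/strand
  segments whose residue identity is a deterministic function of the local
  geometry class and position parity (helix → A/L, strand → V/T). Masked
  tokens are therefore recoverable from structure context alone, giving the
  training loop a signal whose presence (and absence, after coordinate
  shuffling) is independently verifiable with a nearest-neighbour probe.
* `make_landscape()` / `make_landscape_table()` realize an additive fitness
  landscape with wild-type contribution 0, as a log-probability table whose
  differences reproduce the contributions exactly; `score_variant()` on the
  noiseless table recovers the truth with Spearman 1.0, and injected logit
  noise degrades that correlation monotonically.
* `make_fold_change_dataset()` samples labelled variants with fold changes
  `exp(true score)·exp(noise)`, balanced so both label classes are populated.

Passing tests on these fixtures demonstrates that the machinery is correct:
the corruption counts, the invariance contract, the additivity and threshold
identities, the enumeration combinatorics, and that the architecture can learn
a structure-determined sequence signal. They do **not** demonstrate biological
accuracy on real proteins — real fitness landscapes are epistatic, real
structures are not ideal secondary-structure fragments, and the desk-scale
model trained for a few hundred steps has nothing like the capacity or data of
a full-scale pre-trained model. Benchmark-level claims (correlations with deep
mutational scans, clinical-variant classification) require full-scale trained
weights and external datasets and are out of scope here.

## Problem sizes used by the tests and the acceptance script

The training demonstration uses 50 geometry-coded proteins of 48 residues at
context 64, a `K = 64`, 2-layer model, batch 8, 200 steps at base learning
rate 1e-3 with 30 warm-up steps — chosen as the smallest run that reliably
lifts held-out masked-token accuracy far above chance (1/33) while keeping the
whole suite fast on a single CPU. The higher learning rate relative to the
reference schedule is the usual compensation for a much smaller model and far
fewer steps. Invariance is checked over 100 random rigid transforms with
translations up to ±50 Å; Chamfer oracles use random point sets of up to 8
points; replacement-frequency checks aggregate ≥ 20,000 masked positions.

## Known limitations

* Substitutions only: insertions and deletions are not representable in the
  fixed-length token/point alignment.
* Proteins longer than the configured context must be windowed by the caller;
  the package crops but does not stitch overlapping windows.
* The WT-marginal score is additive by construction and therefore blind to
  epistasis between substitutions; the masked-marginal mode relaxes the
  conditioning but not the additivity across sites.
* First chain, first model only when reading multi-chain/multi-model
  structure files; full-atom detail beyond the Cα trace is ignored.
* The canonical frame is undefined for degenerate point sets (fewer than
  three observed points, or exactly isotropic/symmetric clouds); the package
  falls back to a fixed frame there, which preserves validity but not
  equivariance for those inputs.
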