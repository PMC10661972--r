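---
title: "Supervised GRN link prediction with a graph convolutional encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised GRN link prediction with a graph convolutional encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnlink)
```

## The task and its assumptions

`grnlink` predicts directed transcription-factor (TF) → target-gene
regulatory edges by combining two information sources: a single-cell
expression matrix (genes × cells) and an incomplete prior network of known
TF → target interactions. The method assumes that

* regulation leaves a statistical footprint in expression: a target's
  expression co-varies — positively for activation, negatively for
  repression — with its regulator's activity across cells;
* the known edges are a representative (if sparse) sample of the true
  network, so a model fit to them generalizes to the unobserved edges;
* only genes in the supplied TF list can be edge sources.

The model cannot recover regulation that has no expression correlate in the
profiled cells (e.g. post-translational control, or a TF constant across
the captured states), and its decoder is symmetric (see *Limitations*).

## Pipeline

### Preprocessing

Raw expression goes through a fixed sequence:

1. **Low-expression filter.** Genes expressed (value > 0) in less than
   `minCellFraction` (default 10%) of cells are removed; a gene at exactly
   the threshold is kept.
2. **Variance-significance screen.** Each gene's sample variance is
   referred to the dataset's median variance by a chi-square dispersion
   test: s = (M−1)·var_g / median(var) against χ²(M−1), upper tail. No
   specific test is canonical for this screen in the benchmark literature;
   the chi-square dispersion test is a standard highly-variable-gene choice
   and is isolated behind `varianceSignificance()` so it can be swapped.
   Genes with Bonferroni-adjusted p (multiplied by the number of genes
   actually tested, i.e. those surviving step 1) below `alpha` (default
   0.01) are significant; the union of significant TFs and the `topK`
   (default 500) most variable significant genes is kept, ordered by
   decreasing variance.
3. **Log normalization.** x → log₂(x+1). Base 2 is the dominant convention
   for expression data and is configurable (`logBase`).

### Message-passing graph

The encoder propagates features over Ã = D^(−1/2)(A + I)D^(−1/2), where A
is the **symmetrized** binary adjacency of the **training positives only**
plus self-loops. Three deliberate choices:

* *Symmetric normalization.* The D^(−1/2)·D^(−1/2) form is the standard
  GCN operator; it is symmetric with spectral radius ≤ 1, so stacked layers
  cannot amplify features.
* *Training edges only.* Putting validation or test edges into Ã would leak
  the labels being predicted into the features.
* *Symmetrization.* Regulatory information is directional, but expression
  evidence flows both ways along an edge; labels and candidate enumeration
  stay directed TF → gene throughout.

Input self-edges are dropped at read time because the operator adds its own
self-loops; keeping them would double-count.

### Encoder input features

The encoder consumes, per gene, its **absolute co-expression profile**: the
vector of |Pearson correlation| with every gene (computed on the
preprocessed matrix), standardized to zero mean and unit norm per gene
(`coexpressionProfile()`, `trainConfig(features = "coexpression")`). The
reason is structural. The decoder scores pairs by a *rectified* dot product
of nonnegative embeddings, so near initialization the score of a pair is a
positive-semidefinite kernel of the input features — and with raw (or
merely standardized) expression as input, anti-correlated pairs have
negative feature inner products that the rectification maps to zero.
Repression, roughly half of all regulation in a mixed-sign network, would
start invisible, and with only a few hundred labeled pairs training does
not recover it. The absolute co-expression profile makes both regulation
signs equally visible: genes driven by the same regulators have similar
|cor| profiles regardless of sign. The representation is label-free (no
leakage) and is the classic relevance-network featurization of
co-expression analysis. `features = "expression"` feeds the preprocessed
matrix directly for users who want the literal expression features; on
mixed-sign networks it performs markedly worse for the reason above.

Whatever the featurization, the rows of H⁰ are standardized to zero mean
and unit L2 norm, so the input Gram matrix is exactly a correlation matrix
with entries in [−1, 1]. This conditions the optimization: all layer
magnitudes stay O(1) under Glorot initialization and the initial decoder
scores sit below the 0/1 label scale. Without it the first mean-squared-
error steps are so large that every rectified unit dies (the ReLU
subgradient at 0 is 0) and training stalls permanently.

### Encoder, decoder, loss

Each of the L layers computes
`H^(l) = ReLU((λÃ + (1−λ)I) H^(l−1) W^(l−1) + b^(l−1))`; the defaults are
L = 2 with hidden sizes 256 and 128, so embeddings are 128-dimensional. The
mixing weight λ (default 0.4) interpolates between expression-only (0) and
pure graph propagation (1); it enters *every* layer. The decoder is
`R = ReLU(H Hᵀ)`, and the loss is the mean squared error of `R[i,j]`
against binary labels over training positives and hard negatives, plus
`weightDecay · Σ‖W‖²_F` (default 5e-4). Labels are the binary edge
indicator, not a normalized adjacency entry: the sampled pairs are the
supervision, the normalized matrix is the propagation operator.

### Splits and negative sampling

Known edges are split 3:1:1 (train/validation/test) uniformly at random;
base sizes are floors and any remainder is assigned cycling train → val →
test. Training negatives are **hard**: each positive (g₁, g₂) is paired
with (g₁, g₃) sharing the source TF, drawn uniformly from that TF's
non-edges (falling back to the global pool only if the TF's pool is
exhausted). Hard negatives force the model to separate a TF's true targets
from its non-targets instead of merely separating active TFs from silent
genes. Validation and test negatives are uniform draws (TF source,
non-edge) at the count that matches the network density ρ =
|edges| / (|TFs|·(|genes|−1)), i.e. `round(nPos·(1−ρ)/ρ)` negatives, so
evaluation faces the class imbalance a genome-wide screen would face.
Validation uses the same protocol as the test evaluation deliberately:
checkpoint selection should optimize the quantity that is reported. (A
hard-negative validation set was tried during development and is close to
uninformative for selection — hard pairs stay hard at every epoch, so its
AUROC barely moves while generalization rises and falls.) All negative
compartments are mutually disjoint and never contain a known edge.

### Optimization

Full-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), learning rate 0.005, 200
epochs. Gradients are analytic (`lossGradients()`), verified against
central finite differences to 1e-4 relative error in the test suite.
Training runs all epochs and returns the parameters from the epoch with the
highest validation AUROC (earliest on ties) — fixed-length training and
validation-based selection, honoring both conventions at once. Negatives
are sampled once per run, not per epoch. With a few hundred genes a full
run takes seconds on one CPU core; minibatching would add nothing.

### Evaluation and ranking

AUROC is computed from midranks (exact Mann–Whitney with ties counted ½),
so it is invariant under monotone transforms of scores. AUPRC uses the
step-wise (interpolation-free) sweep with tied scores grouped — trapezoidal
interpolation in PR space is optimistically biased and is not used. The
final artifact is the ranked list of all candidate TF → gene pairs
(excluding training positives), ties broken lexicographically so output is
byte-reproducible.

## The synthetic data generator

`simulateGRN()`/`simulateExpression()` emulate the benchmark regime the
pipeline targets, so every stage is testable without downloads:

* **Network.** The edge count is Binomial(nPairs, density) over the
  TF × gene grid (no self-pairs); edges are placed by weighted sampling
  with log-normal(0, 1) per-TF multipliers, producing the heavy-tailed
  out-degrees (hub TFs) of real regulatory networks while keeping the
  realized density concentrated at the requested value.
* **Expression.** Per cell, TF activities are |N(0, 1)|; each target is
  softplus(Σ w·activity) + |N(0, noiseSd)| with per-edge weights
  w ~ N(0, edgeWeightScale²) fixed once — activation and repression in
  equal proportion; TFs express their own activity scaled by
  `edgeWeightScale` (default 2, chosen so TFs are themselves highly
  variable, as the TFs retained in benchmark datasets are). Finally each
  entry is zeroed independently with probability `dropoutRate` — the
  simplest model of false-zero dropout.

Three pinned-seed presets define the study conditions used throughout the
tests: `smoke` (10 TFs / 50 genes / 100 cells / density 0.05), used for
fast plumbing and training-sanity checks; `strong_signal` (25 TFs / 200
genes / 300 cells / density 0.05 / noise 0.1 / dropout 0.2), the recovery
benchmark; `dense` (15 TFs / 100 genes / 200 cells / density 0.4),
mirroring dense cell-type-specific ground truths. These sizes keep a full
five-seed recovery panel under a minute on one core while leaving ~150
edges after preprocessing — enough for a meaningful 3:1:1 split.

What the generator does **not** emulate: counts-specific noise (values are
continuous, not negative binomial), magnitude-dependent dropout, cell
subpopulations or trajectories, TF–TF combinatorial logic, and indirect
(cascade) correlations beyond one regulatory step. Passing the recovery
tests therefore demonstrates that the implementation recovers planted
first-order co-variation structure under dropout at realistic density — it
does not certify performance on real scRNA-seq data, where the paper-style
external benchmarks (ChIP-seq/STRING ground truths) remain the arbiter.

## Numerical choices and degenerate inputs

* Glorot-uniform weight initialization, biases zero, seeded; an
  `outputScale` knob on the final layer is available for unnormalized
  feature experiments.
* ReLU subgradient at exactly 0 is taken as 0 — with nonnegative
  embeddings H, the decoder's ReLU is only active at exact orthogonality,
  and its mask (P > 0) makes the gradient well-defined there.
* Constant genes get zero standardized features (0/0 guarded to 0) and
  p-value 1 in the variance screen; an all-constant matrix is a hard error.
* Isolated nodes in the message-passing graph receive a pure self-loop row.
* Ties in every ranking (ranked edges, candidate lists) break by
  (source, target) lexicographic order; all sampling flows from one seed
  through deterministic per-stage derived seeds, so runs are
  byte-reproducible.
* Degenerate splits (fewer than 5 positives), empty sample lists, empty
  filtered networks, non-finite losses and exhausted negative pools are
  hard errors or loud warnings, never silent.

## Limitations

* The dot-product decoder is symmetric (R = Rᵀ): it cannot represent edge
  direction. Direction comes entirely from restricting candidates and
  labels to TF → gene pairs; within a TF pair (both genes TFs), the model
  cannot say who regulates whom.
* λ's two published roles (propagation weight vs. regularization weight)
  are implemented as *separate* knobs: `lambdaMix` for the encoder mixing
  and `weightDecay` for the Frobenius term, both configurable.
* The variance-significance test is a documented stand-in (see above); a
  rank-only selection is available by raising `alpha` to 1.
* Hard negatives assume unobserved pairs are true negatives; in incomplete
  prior networks some sampled negatives are inevitably unknown positives,
  which biases absolute metric values downward (a property shared by all
  supervised GRN evaluation on incomplete ground truth).
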