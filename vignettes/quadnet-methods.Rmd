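---
title: "Methods: quad-stream attention for protein-protein interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quad-stream attention for protein-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadnet)
```

## The problem

Experimental detection of protein-protein interactions (PPIs) is slow and
incomplete, so computational screening of candidate pairs is a standard step
in systems biology. Modern sequence-based predictors start from protein
language-model embeddings: each protein is summarized as a fixed-length
numeric vector (typically 1024 dimensions) produced by a pretrained
transformer, and a supervised model learns to classify pairs of such vectors
as interacting or not.

`quadnet` implements one such classifier — a quad-stream attention network
with a four-task objective — together with everything around it: robust
scaling of the embedding matrix, pair feature construction and augmentation,
dataset deduplication/balancing/splitting, training and evaluation, exact
nonparametric validation statistics, and a synthetic benchmark generator so
that the whole pipeline is exercisable without any external corpus or
embedder. Embedding generation itself is out of scope: the package consumes
precomputed vectors through an identifier-indexed store, and any external
embedder can be adapted by writing its output in that store format.

## Preprocessing

**Robust scaling.** Language-model embeddings are heavy-tailed: rare
proteins, unusual motifs and disordered regions produce coordinate outliers
that inflate means and standard deviations. The pipeline therefore scales
each embedding dimension by

$$x_{\text{scaled}} = \frac{x - \mathrm{median}(x)}{\mathrm{IQR}(x)},$$

with the interquartile range $Q_3 - Q_1$ computed under the
linear-interpolation (type 7) quantile convention. The convention is
recorded in the scaler's JSON manifest because quartile definitions differ
across software and would otherwise make scalings irreproducible. Dimensions
whose IQR falls below `1e-8` are treated as degenerate: they are centered
but their scale is set to 1 rather than amplifying numerical noise. The
scaler is fitted on the embeddings of proteins occurring in *training*
pairs only — fitting on all data would leak test-set statistics into the
transform.

**Pair features.** From the two scaled embeddings $x_1, x_2$ the pipeline
derives the element-wise product $x_{\text{int}} = x_1 \odot x_2$
(synergistic activation: large where both proteins load on the same
dimension) and the absolute difference $x_{\text{diff}} = |x_1 - x_2|$
(complementary activation: the magnitude of contrast per dimension). Both
are symmetric in the pair, so the derived features do not depend on the
arbitrary order of a pair record.

**Augmentation.** During training, independent Gaussian noise
($\sigma = 0.02$ by default) is added to both scaled embeddings of each
pair, re-drawn every epoch. Noise is applied *before* the product and
difference features are computed, so all four model inputs see a consistent
perturbed pair. At evaluation time augmentation is off.

## The model

Each of the four inputs ($x_1$, $x_2$, $x_{\text{int}}$, $x_{\text{diff}}$)
passes through its own *advanced attention block*:

1. linear projection into a hidden space of width $H$ (default 256);
2. layer normalization;
3. multi-head self-attention ($Q = K = V$, 8 heads) added through a gated
   residual $h_{\text{attn}} = h + \alpha A$ with a learnable scalar
   $\alpha$;
4. a second layer normalization and a GELU feed-forward network
   (expansion 4) with residual connection.

Stream parameters are not shared: each feature type gets specialized
processing. The two protein streams then exchange information through
bidirectional cross-attention (queries from one stream, keys/values from
the other), as do the product and difference streams, with residual
connections preserving the original representations. The four final states
are concatenated and fused by a two-layer GELU network
($4H \to 2H \to H$), and four heads read the fused vector: interaction
probability (sigmoid), uncertainty (softplus, capped), binding strength
(sigmoid), and an interaction-type distribution (softmax over $C$ classes,
default 4).

**Token factorization.** Multi-head attention is defined over sequences,
but the model operates on one pooled vector per protein. A literal reading
— a length-1 sequence — makes softmax attention degenerate: the single
attention weight is identically 1 and the block reduces to a linear map.
The package therefore factors each hidden vector into `nTokens` tokens of
$H/\texttt{nTokens}$ channels (default 8), letting attention mix channel
groups; `nTokens = 1` is retained as the shape-literal mode and both are
tested. Neither interpretation is asserted to be the original authors'
implementation; the factored default is simply the one that gives the
attention mechanism something to attend over.

**Numerical choices.** $\alpha$ is initialized to 0, so every block starts
as a well-conditioned projection-plus-FFN map and attention is switched on
by gradient descent only insofar as it helps; this stabilizes early
training. The uncertainty head is capped at $u_{\max} = 10$: the
uncertainty objective below rewards unbounded uncertainty on misclassified
pairs, and without the cap it diverges (a property demonstrated in the test
suite). Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before
logarithms.

## The four-task objective

With labels $y_i \in \{0,1\}$ and head outputs $p_i, u_i, s_i, t_i$:

* **Interaction**: mean binary cross-entropy of $p_i$ against $y_i$.
* **Uncertainty**: mean of $+u_i$ on correctly classified pairs and
  $-u_i$ on misclassified ones, where the hard label is
  $\hat y_i = \mathbb{1}\{p_i > 0.5\}$ (strict, so $p = 0.5$ maps to 0).
  This pushes uncertainty toward 0 when the model is right and toward the
  cap when it is wrong.
* **Binding strength**: mean squared error of $s_i$ against the
  confidence-derived target $s_{\text{target},i} = 2\,|p_i - 0.5|\,y_i$.
  The target is treated as a constant: no gradient flows through $p_i$ into
  it. A target that moved with the prediction would let the regression
  collapse by dragging the target toward the prediction instead of the
  converse.
* **Type**: with annotated interaction types, mean cross-entropy; without
  (the usual case), the mean KL divergence of each $t_i$ from the uniform
  distribution over $C$ classes — a regularizer that keeps the head active
  in the absence of labels. The KL branch is the default because PPI corpora
  generally carry no type annotation.

The total is $\mathcal{L} = \lambda_1 \mathcal{L}_{\text{interact}} +
\lambda_2 \mathcal{L}_{\text{uncertainty}} + \lambda_3
\mathcal{L}_{\text{binding}} + \lambda_4 \mathcal{L}_{\text{type}}$ with
defaults $(1.0, 0.1, 0.1, 0.1)$: the interaction task dominates and the
auxiliaries act as regularizers. No published weighting exists for this
objective, so the defaults were chosen once on that qualitative ground and
are fully configurable.

Training is implemented natively in R: the forward pass and hand-derived
backward pass (linear, layer-norm, multi-head attention, GELU networks,
all four losses) operate on a flat named parameter list, and every analytic
gradient is verified against central finite differences in the test suite.
Adam, AdamW (decoupled decay) and RMSprop are provided, with
plateau-halving (factor 0.5, patience 5), cosine-annealing and step-decay
(halve every 10 epochs) schedules; these scheduler constants are fixed
package choices recorded in the run manifest. Model selection takes the
epoch with the best validation accuracy; early stopping uses patience 10 on
the same quantity by default. Runs are fully seeded and reproduce
bit-identical histories and checkpoints.

## Dataset handling

Pair tables are canonicalized so each unordered pair appears once
(lexicographic order, first label kept; self-pairs retained). If the same
unordered pair occurs with *conflicting* labels the package refuses rather
than guessing — silent resolution would corrupt evaluation. Balancing is
by undersampling the majority class or oversampling the minority with
replacement.

Splitting is two-stage stratified: first a fully isolated test partition,
then validation versus training, each stage stratifying on the label with
per-class quotas allocated by largest fractional part (deterministic and
order-independent). Sizes follow
$n_{\text{test}} = \lceil 0.12\,n \rceil$ and
$n_{\text{val}} = \mathrm{round}(0.20\,n)$ (half-up). These rounding rules
reproduce all six published partition counts for the 249,814-pair balanced
and 1,082,662-pair oversampled datasets; the alternative reading of the
stage-2 fraction — 0.225 of the remaining 88% — yields 49,463 validation
records instead of the published 49,963, so it is exposed only as the
`valFracRemainder` variant.

Oversampling *before* splitting (the published workflow, and therefore the
default) lets duplicated minority records land on both sides of a split
boundary; `auditLeakage()` counts such crossings and the split manifest
always records them, while `balanceAfterSplit = TRUE` oversamples only the
training partition and audits to zero. Splits are by pair, not by protein:
a protein may occur in several partitions. Homology-aware or
protein-disjoint splitting is deliberately out of scope.

## The synthetic benchmark

`syntheticSpec()` + `simulateBenchmark()` generate an identifier-keyed
embedding store and a labeled pair table with a *planted* interaction rule,
so every downstream stage is testable offline.

* **Embeddings** have i.i.d. coordinates from a Student-t with 3 degrees of
  freedom scaled to unit variance — heavy-tailed with outliers, the regime
  that motivates robust scaling. This emulates tail behaviour only; real
  embedding matrices have correlated coordinates, cluster structure and
  family effects that the generator does not attempt.
* **The rule** scores a pair as $x_a^\top M x_b$ with a symmetric rank-$r$
  matrix $M = \sum_{j=1}^{r} \lambda_j v_j v_j^\top$, $\lambda_j > 0$, and
  labels it interacting when the score exceeds a threshold $\tau$ set to
  the empirical $(1-\texttt{posFrac})$ quantile over a seeded sample of at
  least 10,000 pairs (calibration verified to ±0.02 in the tests). The
  eigenvectors are axis-aligned spikes with a small random admixture
  ($v_j = \sqrt{1-\gamma^2}\, e_{k_j} + \gamma w_j$, $\gamma = 0.05$):
  the planted signal is then dominantly recoverable from the element-wise
  product features (whose diagonal terms carry $(1-\gamma^2)^2 \approx
  99.5\%$ of the bilinear mass) while genuine off-diagonal bilinear
  structure remains. This choice makes the benchmark well-posed — a
  learnable rule is the point of a recovery experiment — and is why a
  linear probe on $[x_{\text{int}}; x_{\text{diff}}]$ already separates
  the classes, a property the test suite asserts.
* **Seeding**: the store, oracle and pair sample derive independent
  sub-seeds from one user seed by fixed offsets, so each artifact can be
  regenerated alone.

Passing the recovery benchmark therefore shows that the implementation can
find a strong planted signal of this specific form at desk scale; it says
nothing about accuracy on real interactome data, which requires the
external corpus and embeddings.

**Problem sizes.** The recovery experiment in the acceptance tests uses
800 proteins, 32 embedding dimensions, 20,000 noise-free pairs, hidden
width 64, batch 256, at most 30 epochs — sizes chosen so the full
experiment (generation, training, evaluation) completes in minutes while
leaving the planted rule clearly recoverable. Unit tests use far smaller
instances.

## Validation statistics

The 2×2 chi-square test of association between predicted and actual classes
uses the plain Pearson statistic $\sum (O-E)^2/E$ (no continuity
correction by default, matching the formula as usually stated; Yates
correction is available behind a flag), with $p$ from the $\chi^2_1$
distribution and effect sizes Cramér's V, $\phi$ and Cohen's $w$ — all
equal to $\sqrt{\chi^2/n}$ for a 2×2 table.

The Wilcoxon signed-rank test is *exact at every n*: zero differences are
dropped, absolute differences are ranked with average ranks for ties, and
the null distribution of $W$ (sum of positive ranks) is built by
generating-function convolution over the realized ranks (doubled onto an
integer lattice so half-ranks from ties are exact). No normal approximation
is used anywhere; under the null the signs remain independent fair coins
even with tied ranks, so the convolution is exact in the tied case too —
which is why a single engine serves all sample sizes, with full $2^n$ sign
enumeration kept as an independent oracle in the tests. For $n = 44$
all-positive differences this yields $W = 990$ and a one-sided
$p = 2^{-44} \approx 5.68 \times 10^{-14}$.

## Known limitations

* The published headline accuracies on the UniProt corpus are not
  reproducible here: they require the 573,661-protein dataset, ProtBERT
  embeddings and large-scale training. The package reproduces the
  *procedures* and verifies them on synthetic data.
* Training is CPU-bound native R; it is comfortable at desk scale
  (tens of thousands of pairs, hidden width ≤ 256) and not intended for
  the million-pair regime.
* The synthetic generator emulates heavy tails and a learnable pairwise
  rule, not biological realism.
* AUC is computed by the tie-aware rank statistic; with heavy score ties
  it equals the trapezoidal ROC area in expectation but individual
  thresholds are not enumerated.
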