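# quadnet

Protein–protein interaction (PPI) prediction from protein language-model
embeddings, for computational biologists who have per-protein embedding
vectors (e.g. 1024-dimensional ProtBERT output) and labeled pair tables,
and want a fully reproducible classifier plus the statistics to validate
it.

## The model

Each candidate pair contributes four feature streams: the two scaled
embeddings **x**₁ and **x**₂, their element-wise product
**x**ᵢₙₜ = **x**₁ ⊙ **x**₂ (synergistic activation) and their absolute
difference **x**_diff = |**x**₁ − **x**₂| (complementary activation).
Every stream passes through its own attention block

&nbsp;&nbsp;**h** = Linear(**x**), &nbsp;
**h**ₐ = **h** + α · MultiHead(LN(**h**)), &nbsp;
**h**_final = **h**ₐ + FFN(LN(**h**ₐ)),

with 8-head scaled dot-product attention and a learnable residual gate α.
Bidirectional cross-attention exchanges information between the two protein
streams and between the product/difference streams; the four final states
are concatenated and fused by a two-layer GELU network, and four heads
predict per pair: interaction probability p (sigmoid), uncertainty u
(capped softplus), binding strength s (sigmoid), and an interaction-type
distribution **t** (softmax). Training minimizes

&nbsp;&nbsp;ℒ = λ₁ ℒ_interact + λ₂ ℒ_uncertainty + λ₃ ℒ_binding + λ₄ ℒ_type,

binary cross-entropy on p, a ±u calibration term keyed to
ŷ = 1{p > 0.5}, MSE of s against the stop-gradient target
s_target = 2·|p − 0.5|·y, and KL(t ‖ uniform) when type labels are absent.

Around the model the package provides robust median/IQR scaling, Gaussian
noise augmentation (σ = 0.02), pair deduplication and balancing, the
two-stage stratified train/validation/test split (12% test, 20%
validation), Adam/AdamW/RMSprop with plateau/cosine/step schedules, the
five standard metrics, a 2×2 χ² association test with Cramér's V / φ /
Cohen's w, an exact (convolution-based, tie-aware) Wilcoxon signed-rank
test, and a seeded synthetic benchmark generator with a planted symmetric
bilinear interaction rule. The forward and backward passes are implemented
natively in R and verified against finite differences in the test suite.

## Worked example

```r
library(quadnet)

## a synthetic benchmark: heavy-tailed embeddings + planted bilinear rule
spec   <- syntheticSpec(nProteins = 300, dim = 16, ruleRank = 3, seed = 11)
bench  <- simulateBenchmark(spec, nPairs = 4000)
bench$pairs
#> PairTable: 4000 pairs (2038 positive, 1962 negative)

splits <- twoStageStratifiedSplit(bench$pairs,
                                  computeSplitSizes(length(bench$pairs)),
                                  seed = 5)
splits
#> DatasetSplits: train 2720 / val 800 / test 480

cfg <- attentionConfig(inputDim = 16, hiddenDim = 32, numHeads = 8,
                       nTokens = 4)
tc  <- trainingConfig(optimizer = "adamw", learningRate = 1e-3,
                      weightDecay = 1e-4, scheduler = "plateau",
                      batchSize = 128, maxEpochs = 10, seed = 7)
fit <- trainQuadNet(initQuadNet(cfg, seed = 2), bench$store, splits, tc)

evaluateModel(fit$model, testSet(splits), bench$store, fit$scaler)
#> Metrics on 480 pairs:
#>   accuracy 90.42%  precision 91.98%  recall 88.98%  F1 90.46%  AUC-ROC 97.74%
#>   confusion: TP 218  FP 19  TN 216  FN 27
```

Ten epochs on a small planted benchmark already recover most of the rule:
90% of held-out pairs are classified correctly and the ranking is nearly
perfect (AUC ≈ 98%). The acceptance suite runs the full-size recovery
experiment (20,000 pairs, 32 dimensions, hidden width 64), which reaches
≥ 95% held-out accuracy.

Validation statistics work on any predictions:

```r
wilcoxonSignedRankExact(1:44)
#> Exact Wilcoxon signed-rank: W = 990 on 44 nonzero differences
#>   one-sided p = 5.684e-14, two-sided p = 1.137e-13

chiSquare2x2(matrix(c(10, 0, 0, 10), 2))
#> Chi-square association (2x2): chi2 = 20, df = 1, p = 7.744e-06
#>   Cramer's V = phi = Cohen's w = 1 (n = 20)
```

A thin command-line wrapper over these functions lives in
`inst/cli/quadnet.R` (subcommands: `simulate`, `split`, `preprocess`,
`train`, `evaluate`, `predict`, `stats-chi2`, `stats-wilcoxon`).

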