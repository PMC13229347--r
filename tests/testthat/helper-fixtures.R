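# Shared fixtures: tiny model configurations and an independent
# loop-based multi-head attention oracle.

tinyCfg <- function(inputDim = 6L, hiddenDim = 8L, numHeads = 2L,
                    nTokens = 2L, ffnExpansion = 2L, dropout = 0,
                    numTypes = 3L, uMax = 10) {
  attentionConfig(inputDim = inputDim, hiddenDim = hiddenDim,
                  numHeads = numHeads, nTokens = nTokens,
                  ffnExpansion = ffnExpansion, dropout = dropout,
                  numTypes = numTypes, uMax = uMax)
}

tinyModel <- function(cfg = tinyCfg(), seed = 3L) initQuadNet(cfg, seed = seed)

randomBundle <- function(B, D, seed = 1L) {
  set.seed(seed)
  x1 <- matrix(rnorm(B * D), B)
  x2 <- matrix(rnorm(B * D), B)
  list(x1 = x1, x2 = x2, xInt = x1 * x2, xDiff = abs(x1 - x2))
}

# Independent multi-head attention oracle: explicit per-sample, per-head,
# per-token loops straight from the definition (softmax(QK'/sqrt(dk)) V,
# heads concatenated, projected by Wo). Deliberately naive.
naiveMHA <- function(Xq, Xkv, W, cfg) {
  Tn <- cfg$nTokens; Ch <- cfg$channels; nh <- cfg$numHeads; dk <- cfg$dK
  B <- nrow(Xq)
  out <- matrix(0, B, cfg$hiddenDim)
  for (b in seq_len(B)) {
    tokQ <- lapply(seq_len(Tn), function(t) Xq[b, ((t - 1) * Ch + 1):(t * Ch)])
    tokK <- lapply(seq_len(Tn), function(t) Xkv[b, ((t - 1) * Ch + 1):(t * Ch)])
    for (i in seq_len(Tn)) {
      Oi <- numeric(Ch)
      for (h in seq_len(nh)) {
        hc <- ((h - 1) * dk + 1):(h * dk)
        q <- drop(tokQ[[i]] %*% W$Wq)[hc]
        scores <- vapply(seq_len(Tn), function(j) {
          k <- drop(tokK[[j]] %*% W$Wk)[hc]
          sum(q * k) / sqrt(dk)
        }, numeric(1))
        pr <- exp(scores - max(scores))
        pr <- pr / sum(pr)
        acc <- numeric(dk)
        for (j in seq_len(Tn)) {
          v <- drop(tokK[[j]] %*% W$Wv)[hc]
          acc <- acc + pr[j] * v
        }
        Oi[hc] <- acc
      }
      out[b, ((i - 1) * Ch + 1):(i * Ch)] <- Oi %*% W$Wo
    }
  }
  out
}

attnWeights <- function(model, which = "s1.attn") {
  p <- modelParams(model)
  list(Wq = p[[paste0(which, ".Wq")]], Wk = p[[paste0(which, ".Wk")]],
       Wv = p[[paste0(which, ".Wv")]], Wo = p[[paste0(which, ".Wo")]])
}

# Small synthetic benchmark used by several training tests.
smallBenchmark <- function(nProteins = 120L, dim = 8L, nPairs = 400L,
                           seed = 9L, ...) {
  spec <- syntheticSpec(nProteins = nProteins, dim = dim, ruleRank = 2L,
                        posFrac = 0.5, seed = seed, ...)
  simulateBenchmark(spec, nPairs = nPairs)
}
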