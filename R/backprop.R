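## Hand-derived backward pass of the quad-stream network. Consumes the
## forward cache from quadnetForwardCore() and head-preactivation gradients
## from the loss, and returns a gradient list with the same names/shapes as
## the parameter list. Verified against central finite differences in the
## test suite.

streamBackwardCore <- function(dOut, p, s, cfg, cache) {
  g <- list()
  ## FFN residual: out = hAttn + hff
  dHff <- dOut
  g[[paste0(s, ".ffn.b2")]] <- colSums(dHff)
  g[[paste0(s, ".ffn.W2")]] <- crossprod(cache$a1d, dHff)
  dA1d <- tcrossprod(dHff, p[[paste0(s, ".ffn.W2")]])
  dA1 <- if (is.null(cache$maskF)) dA1d else dA1d * cache$maskF
  dF1 <- dA1 * (cache$phiF + cache$f1 * stats::dnorm(cache$f1))
  g[[paste0(s, ".ffn.b1")]] <- colSums(dF1)
  g[[paste0(s, ".ffn.W1")]] <- crossprod(cache$ln2$y, dF1)
  dLn2y <- tcrossprod(dF1, p[[paste0(s, ".ffn.W1")]])
  ln2b <- layerNormBackward(dLn2y, cache$ln2, p[[paste0(s, ".ln2.g")]])
  g[[paste0(s, ".ln2.g")]] <- ln2b$dg
  g[[paste0(s, ".ln2.b")]] <- ln2b$db
  dHattn <- dOut + ln2b$dx
  ## gated attention residual: hAttn = h + alpha * Ad
  alpha <- p[[paste0(s, ".alpha")]]
  g[[paste0(s, ".alpha")]] <- sum(dHattn * cache$Ad)
  dAd <- dHattn * alpha
  dA <- if (is.null(cache$maskA)) dAd else dAd * cache$maskA
  W <- list(Wq = p[[paste0(s, ".attn.Wq")]], Wk = p[[paste0(s, ".attn.Wk")]],
            Wv = p[[paste0(s, ".attn.Wv")]], Wo = p[[paste0(s, ".attn.Wo")]])
  mb <- mhaBackwardCore(dA, W, cache$att, cfg)
  g[[paste0(s, ".attn.Wq")]] <- mb$dWq
  g[[paste0(s, ".attn.Wk")]] <- mb$dWk
  g[[paste0(s, ".attn.Wv")]] <- mb$dWv
  g[[paste0(s, ".attn.Wo")]] <- mb$dWo
  dLn1y <- mb$dXq + mb$dXkv  # self-attention: Q and K/V share the input
  ln1b <- layerNormBackward(dLn1y, cache$ln1, p[[paste0(s, ".ln1.g")]])
  g[[paste0(s, ".ln1.g")]] <- ln1b$dg
  g[[paste0(s, ".ln1.b")]] <- ln1b$db
  dH <- dHattn + ln1b$dx
  g[[paste0(s, ".proj.b")]] <- colSums(dH)
  g[[paste0(s, ".proj.W")]] <- crossprod(cache$X, dH)
  g
}

## dZ: list with head-preactivation gradients dzp, dzu, dzs, dzt (already
## including loss weights and the 1/N batch normalization).
quadnetBackwardCore <- function(params, cache, dZ, cfg) {
  g <- list()
  hf <- cache$fusion  # fusion cache
  B <- nrow(hf$hc)
  ## heads
  dHf <- matrix(0, B, cfg$hiddenDim)
  headIn <- hf$hf  # fused representation
  g[["head.int.W"]] <- crossprod(headIn, matrix(dZ$dzp, ncol = 1L))
  g[["head.int.b"]] <- sum(dZ$dzp)
  dHf <- dHf + tcrossprod(matrix(dZ$dzp, ncol = 1L), params[["head.int.W"]])
  g[["head.unc.W"]] <- crossprod(headIn, matrix(dZ$dzu, ncol = 1L))
  g[["head.unc.b"]] <- sum(dZ$dzu)
  dHf <- dHf + tcrossprod(matrix(dZ$dzu, ncol = 1L), params[["head.unc.W"]])
  g[["head.bind.W"]] <- crossprod(headIn, matrix(dZ$dzs, ncol = 1L))
  g[["head.bind.b"]] <- sum(dZ$dzs)
  dHf <- dHf + tcrossprod(matrix(dZ$dzs, ncol = 1L), params[["head.bind.W"]])
  g[["head.type.W"]] <- crossprod(headIn, dZ$dzt)
  g[["head.type.b"]] <- colSums(dZ$dzt)
  dHf <- dHf + tcrossprod(dZ$dzt, params[["head.type.W"]])
  ## fusion: hf = gelu(z2), z2 = g1 W2 + b2, g1 = gelu(z1), z1 = hc W1 + b1
  dZ2 <- dHf * (hf$phi2 + hf$z2 * stats::dnorm(hf$z2))
  g[["fusion.b2"]] <- colSums(dZ2)
  g[["fusion.W2"]] <- crossprod(hf$g1, dZ2)
  dG1 <- tcrossprod(dZ2, params[["fusion.W2"]])
  dZ1 <- dG1 * (hf$phi1 + hf$z1 * stats::dnorm(hf$z1))
  g[["fusion.b1"]] <- colSums(dZ1)
  g[["fusion.W1"]] <- crossprod(hf$hc, dZ1)
  dHc <- tcrossprod(dZ1, params[["fusion.W1"]])
  H <- cfg$hiddenDim
  dFinals <- list(h1 = dHc[, 1:H, drop = FALSE],
                  h2 = dHc[, (H + 1):(2 * H), drop = FALSE],
                  hint = dHc[, (2 * H + 1):(3 * H), drop = FALSE],
                  hdiff = dHc[, (3 * H + 1):(4 * H), drop = FALSE])
  ## cross-attention: final_q = stream_q + MHA(stream_q, stream_kv)
  dStreams <- dFinals  # residual path
  for (cn in crossNames) {
    plan <- crossPlan[[cn]]
    W <- list(Wq = params[[paste0(cn, ".Wq")]], Wk = params[[paste0(cn, ".Wk")]],
              Wv = params[[paste0(cn, ".Wv")]], Wo = params[[paste0(cn, ".Wo")]])
    mb <- mhaBackwardCore(dFinals[[plan[["q"]]]], W, cache$cross[[cn]], cfg)
    g[[paste0(cn, ".Wq")]] <- mb$dWq
    g[[paste0(cn, ".Wk")]] <- mb$dWk
    g[[paste0(cn, ".Wv")]] <- mb$dWv
    g[[paste0(cn, ".Wo")]] <- mb$dWo
    dStreams[[plan[["q"]]]] <- dStreams[[plan[["q"]]]] + mb$dXq
    dStreams[[plan[["kv"]]]] <- dStreams[[plan[["kv"]]]] + mb$dXkv
  }
  ## per-stream attention blocks
  outName <- c(s1 = "h1", s2 = "h2", sint = "hint", sdiff = "hdiff")
  for (s in streamNames) {
    g <- c(g, streamBackwardCore(dStreams[[outName[[s]]]], params, s, cfg,
                                 cache$streams[[s]]))
  }
  g
}
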