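## The quad-stream attention network: architecture configuration,
## parameter initialization, and the forward pass. Gradients live in
## backprop.R; both operate on a flat named list of parameter arrays so the
## optimizers can treat the model generically.

#' Architecture configuration for the quad-stream attention network
#'
#' Each of the four feature streams (protein 1, protein 2, element-wise
#' product, absolute difference) is projected from `inputDim` to
#' `hiddenDim`, then processed by a gated multi-head self-attention block
#' and exchanged through cross-attention. Multi-head attention operates on
#' a token factorization of the hidden vector: the `hiddenDim` channels are
#' reshaped into `nTokens` tokens of `hiddenDim / nTokens` channels, and
#' attention mixes the token groups (`nTokens = 1` degenerates to a single
#' attended position, where softmax over one score is identically 1 and
#' attention reduces to a linear map; both modes are supported).
#'
#' @param inputDim dimensionality of the (scaled) embedding vectors.
#' @param hiddenDim hidden width (default 256); must be divisible by
#'   `nTokens`, and the per-token channel count by `numHeads`.
#' @param numHeads attention heads (default 8).
#' @param nTokens tokens the hidden vector is factored into (default 8).
#' @param ffnExpansion feed-forward expansion factor (default 4).
#' @param dropout dropout probability during training (default 0.1).
#' @param numTypes number of interaction-type classes C (default 4).
#' @param uMax cap on the uncertainty head output; keeps the reward for
#'   high uncertainty on misclassified pairs bounded (default 10).
#' @return validated configuration list of class `AttentionConfig`.
#' @export
attentionConfig <- function(inputDim, hiddenDim = 256L, numHeads = 8L,
                            nTokens = 8L, ffnExpansion = 4L, dropout = 0.1,
                            numTypes = 4L, uMax = 10) {
  inputDim <- assertCount(inputDim, "inputDim")
  hiddenDim <- assertCount(hiddenDim, "hiddenDim")
  numHeads <- assertCount(numHeads, "numHeads")
  nTokens <- assertCount(nTokens, "nTokens")
  if (hiddenDim %% nTokens != 0L) {
    stopf("hiddenDim (%d) must be divisible by nTokens (%d)", hiddenDim, nTokens)
  }
  channels <- hiddenDim %/% nTokens
  if (channels %% numHeads != 0L) {
    stopf("per-token channels (%d) must be divisible by numHeads (%d)",
          channels, numHeads)
  }
  assertFraction(dropout, "dropout", lo = 0, hi = 1, openLo = FALSE)
  structure(list(inputDim = inputDim, hiddenDim = hiddenDim,
                 numHeads = numHeads, nTokens = nTokens,
                 channels = channels, dK = channels %/% numHeads,
                 ffnExpansion = assertCount(ffnExpansion, "ffnExpansion"),
                 dropout = dropout,
                 numTypes = assertCount(numTypes, "numTypes", min = 2L),
                 uMax = assertFraction(uMax, "uMax", lo = 0, hi = Inf)),
            class = "AttentionConfig")
}

xavierInit <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

streamNames <- c("s1", "s2", "sint", "sdiff")
crossNames <- c("c1", "c2", "cint", "cdiff")

#' Initialize a quad-stream attention model
#'
#' Creates all parameters: per-stream input projection, layer norms,
#' self-attention projections, learnable residual gate alpha (initialized
#' to 0, so each block starts as an identity-plus-FFN map), feed-forward
#' weights; four cross-attention modules; the two-layer fusion network; and
#' the four task heads. Stream parameters are not shared across streams,
#' allowing specialized processing per feature type.
#'
#' @param config an [attentionConfig()].
#' @param seed RNG seed for the initialization draw.
#' @return A [QuadNetModel-class].
#' @examples
#' m <- initQuadNet(attentionConfig(inputDim = 16, hiddenDim = 32), seed = 1)
#' m
#' @export
initQuadNet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "AttentionConfig"))
  set.seed(seed)
  H <- config$hiddenDim; D <- config$inputDim
  Ch <- config$channels; Ff <- H * config$ffnExpansion
  C <- config$numTypes
  p <- list()
  attnSet <- function() list(Wq = xavierInit(Ch, Ch), Wk = xavierInit(Ch, Ch),
                             Wv = xavierInit(Ch, Ch), Wo = xavierInit(Ch, Ch))
  for (s in streamNames) {
    p[[paste0(s, ".proj.W")]] <- xavierInit(D, H)
    p[[paste0(s, ".proj.b")]] <- numeric(H)
    p[[paste0(s, ".ln1.g")]] <- rep(1, H)
    p[[paste0(s, ".ln1.b")]] <- numeric(H)
    a <- attnSet()
    p[[paste0(s, ".attn.Wq")]] <- a$Wq
    p[[paste0(s, ".attn.Wk")]] <- a$Wk
    p[[paste0(s, ".attn.Wv")]] <- a$Wv
    p[[paste0(s, ".attn.Wo")]] <- a$Wo
    p[[paste0(s, ".alpha")]] <- 0
    p[[paste0(s, ".ln2.g")]] <- rep(1, H)
    p[[paste0(s, ".ln2.b")]] <- numeric(H)
    p[[paste0(s, ".ffn.W1")]] <- xavierInit(H, Ff)
    p[[paste0(s, ".ffn.b1")]] <- numeric(Ff)
    p[[paste0(s, ".ffn.W2")]] <- xavierInit(Ff, H)
    p[[paste0(s, ".ffn.b2")]] <- numeric(H)
  }
  for (s in crossNames) {
    a <- attnSet()
    p[[paste0(s, ".Wq")]] <- a$Wq
    p[[paste0(s, ".Wk")]] <- a$Wk
    p[[paste0(s, ".Wv")]] <- a$Wv
    p[[paste0(s, ".Wo")]] <- a$Wo
  }
  p[["fusion.W1"]] <- xavierInit(4L * H, 2L * H)
  p[["fusion.b1"]] <- numeric(2L * H)
  p[["fusion.W2"]] <- xavierInit(2L * H, H)
  p[["fusion.b2"]] <- numeric(H)
  p[["head.int.W"]] <- xavierInit(H, 1L)
  p[["head.int.b"]] <- 0
  p[["head.unc.W"]] <- xavierInit(H, 1L)
  p[["head.unc.b"]] <- 0
  p[["head.bind.W"]] <- xavierInit(H, 1L)
  p[["head.bind.b"]] <- 0
  p[["head.type.W"]] <- xavierInit(H, C)
  p[["head.type.b"]] <- numeric(C)
  new("QuadNetModel", params = p, config = unclass(config))
}

#' Replace the parameters of a model
#'
#' @param model a [QuadNetModel-class].
#' @param params named list matching the model's parameter layout.
#' @return the model with `params` substituted.
#' @export
withParams <- function(model, params) {
  new("QuadNetModel", params = params, config = modelConfig(model))
}

## ---- layer norm ----

lnEps <- 1e-5

layerNormForward <- function(h, g, b) {
  mu <- rowMeans(h)
  hc <- h - mu
  v <- rowMeans(hc * hc)
  invsd <- 1 / sqrt(v + lnEps)
  xhat <- hc * invsd
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(y = y, xhat = xhat, invsd = invsd)
}

layerNormBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, g, "*")
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$invsd
  list(dx = dx, dg = dg, db = db)
}

## ---- multi-head attention over token-factored hidden vectors ----

tokCols <- function(cfg) {
  lapply(seq_len(cfg$nTokens),
         function(t) ((t - 1L) * cfg$channels + 1L):(t * cfg$channels))
}

## Ch x numHeads indicator summing channels within each head.
headSumMat <- function(cfg) {
  Mh <- matrix(0, cfg$channels, cfg$numHeads)
  for (h in seq_len(cfg$numHeads)) {
    Mh[((h - 1L) * cfg$dK + 1L):(h * cfg$dK), h] <- 1
  }
  Mh
}

mhaForwardCore <- function(Xq, Xkv, W, cfg) {
  Tn <- cfg$nTokens
  cols <- tokCols(cfg)
  expandIdx <- rep(seq_len(cfg$numHeads), each = cfg$dK)
  Mh <- headSumMat(cfg)
  scal <- 1 / sqrt(cfg$dK)
  B <- nrow(Xq)
  Qt <- Kt <- Vt <- vector("list", Tn)
  Xqt <- Xkt <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xqt[[t]] <- Xq[, cols[[t]], drop = FALSE]
    Xkt[[t]] <- Xkv[, cols[[t]], drop = FALSE]
    Qt[[t]] <- Xqt[[t]] %*% W$Wq
    Kt[[t]] <- Xkt[[t]] %*% W$Wk
    Vt[[t]] <- Xkt[[t]] %*% W$Wv
  }
  P <- Ot <- vector("list", Tn)
  out <- matrix(0, B, cfg$hiddenDim)
  ## P[[i]][[j]]: batch x heads attention probabilities, query token i over
  ## key token j (lists of matrices avoid repeated 3D-array slicing)
  for (i in seq_len(Tn)) {
    S <- vector("list", Tn)
    for (j in seq_len(Tn)) {
      S[[j]] <- ((Qt[[i]] * Kt[[j]]) %*% Mh) * scal
    }
    ## softmax over the key axis j, per (row, head)
    M <- Reduce(pmax, S)
    Pi <- lapply(S, function(s) exp(s - M))
    den <- Reduce(`+`, Pi)
    Oi <- matrix(0, B, cfg$channels)
    for (j in seq_len(Tn)) {
      Pi[[j]] <- Pi[[j]] / den
      Oi <- Oi + Pi[[j]][, expandIdx, drop = FALSE] * Vt[[j]]
    }
    P[[i]] <- Pi
    Ot[[i]] <- Oi
    out[, cols[[i]]] <- Oi %*% W$Wo
  }
  list(out = out,
       cache = list(Xqt = Xqt, Xkt = Xkt, Qt = Qt, Kt = Kt, Vt = Vt,
                    P = P, Ot = Ot))
}

mhaBackwardCore <- function(dOut, W, cache, cfg) {
  Tn <- cfg$nTokens
  cols <- tokCols(cfg)
  expandIdx <- rep(seq_len(cfg$numHeads), each = cfg$dK)
  Mh <- headSumMat(cfg)
  scal <- 1 / sqrt(cfg$dK)
  B <- nrow(dOut)
  dWq <- dWk <- dWv <- dWo <- matrix(0, cfg$channels, cfg$channels)
  dQt <- lapply(seq_len(Tn), function(t) matrix(0, B, cfg$channels))
  dKt <- lapply(seq_len(Tn), function(t) matrix(0, B, cfg$channels))
  dVt <- lapply(seq_len(Tn), function(t) matrix(0, B, cfg$channels))
  nh <- cfg$numHeads
  for (i in seq_len(Tn)) {
    dOuti <- dOut[, cols[[i]], drop = FALSE]
    dWo <- dWo + crossprod(cache$Ot[[i]], dOuti)
    dOi <- tcrossprod(dOuti, W$Wo)
    Pi <- cache$P[[i]]
    dPi <- vector("list", Tn)
    for (j in seq_len(Tn)) {
      dPi[[j]] <- (dOi * cache$Vt[[j]]) %*% Mh
      dVt[[j]] <- dVt[[j]] + Pi[[j]][, expandIdx, drop = FALSE] * dOi
    }
    rs <- matrix(0, B, nh)
    for (j in seq_len(Tn)) rs <- rs + dPi[[j]] * Pi[[j]]
    for (j in seq_len(Tn)) {
      dSij <- Pi[[j]] * (dPi[[j]] - rs)
      dSe <- dSij[, expandIdx, drop = FALSE] * scal
      dQt[[i]] <- dQt[[i]] + dSe * cache$Kt[[j]]
      dKt[[j]] <- dKt[[j]] + dSe * cache$Qt[[i]]
    }
  }
  dXq <- matrix(0, B, cfg$hiddenDim)
  dXkv <- matrix(0, B, cfg$hiddenDim)
  for (t in seq_len(Tn)) {
    dWq <- dWq + crossprod(cache$Xqt[[t]], dQt[[t]])
    dWk <- dWk + crossprod(cache$Xkt[[t]], dKt[[t]])
    dWv <- dWv + crossprod(cache$Xkt[[t]], dVt[[t]])
    dXq[, cols[[t]]] <- tcrossprod(dQt[[t]], W$Wq)
    dXkv[, cols[[t]]] <- tcrossprod(dKt[[t]], W$Wk) + tcrossprod(dVt[[t]], W$Wv)
  }
  list(dXq = dXq, dXkv = dXkv, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

#' Multi-head scaled dot-product attention over token-factored vectors
#'
#' Queries come from `Xq`, keys and values from `Xkv` (self-attention when
#' they coincide). Each hidden vector is factored into `nTokens` tokens;
#' per head, scores are `Q K' / sqrt(dK)`, softmax-normalized over keys,
#' applied to V, then heads are concatenated and projected by `Wo`.
#'
#' @param Xq,Xkv numeric matrices (batch x hiddenDim).
#' @param weights list with per-token-channel projection matrices `Wq`,
#'   `Wk`, `Wv`, `Wo` (each channels x channels).
#' @param config an [attentionConfig()] (only the shape fields are used).
#' @param returnWeights if TRUE, also return the attention probabilities
#'   as a nested list (query token, then key token) of batch x heads
#'   matrices.
#' @return the attended output (batch x hiddenDim), or a list
#'   `(output, weights)` when `returnWeights = TRUE`.
#' @export
multiHeadAttention <- function(Xq, Xkv, weights, config, returnWeights = FALSE) {
  if (ncol(Xq) != config$hiddenDim || ncol(Xkv) != config$hiddenDim) {
    stopf("inputs must have %d columns (hiddenDim)", config$hiddenDim)
  }
  r <- mhaForwardCore(Xq, Xkv, weights, config)
  if (returnWeights) list(output = r$out, weights = r$cache$P) else r$out
}

## ---- dropout ----

dropoutMask <- function(n, p) {
  (stats::runif(n) >= p) / (1 - p)
}

## ---- stream (advanced attention block) ----

streamForwardCore <- function(X, p, s, cfg, training = FALSE) {
  W <- list(Wq = p[[paste0(s, ".attn.Wq")]], Wk = p[[paste0(s, ".attn.Wk")]],
            Wv = p[[paste0(s, ".attn.Wv")]], Wo = p[[paste0(s, ".attn.Wo")]])
  h <- sweep(X %*% p[[paste0(s, ".proj.W")]], 2L, p[[paste0(s, ".proj.b")]], "+")
  ln1 <- layerNormForward(h, p[[paste0(s, ".ln1.g")]], p[[paste0(s, ".ln1.b")]])
  att <- mhaForwardCore(ln1$y, ln1$y, W, cfg)
  A <- att$out
  maskA <- NULL
  Ad <- A
  if (training && cfg$dropout > 0) {
    maskA <- matrix(dropoutMask(length(A), cfg$dropout), nrow(A), ncol(A))
    Ad <- A * maskA
  }
  hAttn <- h + p[[paste0(s, ".alpha")]] * Ad
  ln2 <- layerNormForward(hAttn, p[[paste0(s, ".ln2.g")]], p[[paste0(s, ".ln2.b")]])
  f1 <- sweep(ln2$y %*% p[[paste0(s, ".ffn.W1")]], 2L, p[[paste0(s, ".ffn.b1")]], "+")
  phiF <- stats::pnorm(f1)
  a1 <- f1 * phiF
  maskF <- NULL
  a1d <- a1
  if (training && cfg$dropout > 0) {
    maskF <- matrix(dropoutMask(length(a1), cfg$dropout), nrow(a1), ncol(a1))
    a1d <- a1 * maskF
  }
  hff <- sweep(a1d %*% p[[paste0(s, ".ffn.W2")]], 2L, p[[paste0(s, ".ffn.b2")]], "+")
  out <- hAttn + hff
  list(out = out,
       cache = list(X = X, h = h, ln1 = ln1, att = att$cache, A = A, Ad = Ad,
                    maskA = maskA, hAttn = hAttn, ln2 = ln2, f1 = f1,
                    phiF = phiF, a1 = a1, a1d = a1d, maskF = maskF))
}

#' Advanced attention block forward pass
#'
#' One stream of the network: linear projection into the hidden space,
#' layer normalization, gated multi-head self-attention
#' (`h + alpha * Attention(LN(h))` with learnable scalar `alpha`), a second
#' layer normalization, and a GELU feed-forward network with residual
#' connection.
#'
#' @param x input matrix (batch x inputDim).
#' @param model a [QuadNetModel-class].
#' @param stream one of `"s1"`, `"s2"`, `"sint"`, `"sdiff"`.
#' @param training if TRUE, dropout is active.
#' @return hidden representation (batch x hiddenDim).
#' @export
attentionBlockForward <- function(x, model, stream = "s1", training = FALSE) {
  stopifnot(stream %in% streamNames)
  cfg <- modelConfig(model)
  if (ncol(x) != cfg$inputDim) {
    stopf("input has %d columns, model expects %d", ncol(x), cfg$inputDim)
  }
  streamForwardCore(x, modelParams(model), stream, cfg, training = training)$out
}

## ---- cross-attention exchange ----

crossPlan <- list(c1 = c(q = "h1", kv = "h2"), c2 = c(q = "h2", kv = "h1"),
                  cint = c(q = "hint", kv = "hdiff"),
                  cdiff = c(q = "hdiff", kv = "hint"))

crossForwardCore <- function(streams, p, cfg) {
  caches <- list()
  finals <- list()
  for (cn in crossNames) {
    W <- list(Wq = p[[paste0(cn, ".Wq")]], Wk = p[[paste0(cn, ".Wk")]],
              Wv = p[[paste0(cn, ".Wv")]], Wo = p[[paste0(cn, ".Wo")]])
    plan <- crossPlan[[cn]]
    r <- mhaForwardCore(streams[[plan[["q"]]]], streams[[plan[["kv"]]]], W, cfg)
    finals[[plan[["q"]]]] <- streams[[plan[["q"]]]] + r$out
    caches[[cn]] <- r$cache
  }
  list(finals = finals, caches = caches)
}

#' Bidirectional cross-attention exchange between streams
#'
#' Protein cross-attention exchanges information between the two protein
#' streams (queries from one, keys/values from the other, in both
#' directions); feature cross-attention does the same between the product
#' and difference streams. Residual connections preserve the original
#' stream representations: `h_i_final = h_i + CrossAttention(h_i, h_j, h_j)`.
#'
#' @param streams named list with matrices `h1`, `h2`, `hint`, `hdiff`
#'   (each batch x hiddenDim).
#' @param model a [QuadNetModel-class].
#' @return named list of the four final stream states (same shapes).
#' @export
crossAttentionExchange <- function(streams, model) {
  need <- c("h1", "h2", "hint", "hdiff")
  if (!all(need %in% names(streams))) {
    stopf("missing stream(s): %s", paste(setdiff(need, names(streams)), collapse = ", "))
  }
  crossForwardCore(streams, modelParams(model), modelConfig(model))$finals
}

## ---- quad-stream fusion ----

fusionForwardCore <- function(finals, p) {
  hc <- cbind(finals$h1, finals$h2, finals$hint, finals$hdiff)
  z1 <- sweep(hc %*% p[["fusion.W1"]], 2L, p[["fusion.b1"]], "+")
  phi1 <- stats::pnorm(z1)
  g1 <- z1 * phi1
  z2 <- sweep(g1 %*% p[["fusion.W2"]], 2L, p[["fusion.b2"]], "+")
  phi2 <- stats::pnorm(z2)
  hf <- z2 * phi2
  list(hf = hf, cache = list(hc = hc, z1 = z1, phi1 = phi1, g1 = g1,
                             z2 = z2, phi2 = phi2, hf = hf))
}

#' Fuse the four stream representations
#'
#' Concatenates the four final stream states into a 4 x hiddenDim-wide
#' feature vector per pair, then applies the two-layer GELU fusion network
#' `GELU(W2 GELU(W1 h + b1) + b2)` mapping through 2 x hiddenDim back to
#' hiddenDim. Concatenation is ordered, so the fusion is sensitive to
#' stream order by construction.
#'
#' @param streams named list with `h1`, `h2`, `hint`, `hdiff` final states.
#' @param model a [QuadNetModel-class].
#' @return fused representation (batch x hiddenDim).
#' @export
quadFusion <- function(streams, model) {
  fusionForwardCore(streams, modelParams(model))$hf
}

## ---- task heads ----

headsForwardCore <- function(hf, p, cfg) {
  zp <- drop(hf %*% p[["head.int.W"]]) + p[["head.int.b"]]
  zu <- drop(hf %*% p[["head.unc.W"]]) + p[["head.unc.b"]]
  zs <- drop(hf %*% p[["head.bind.W"]]) + p[["head.bind.b"]]
  zt <- sweep(hf %*% p[["head.type.W"]], 2L, p[["head.type.b"]], "+")
  uraw <- softplus(zu)
  list(p = sigmoid(zp), u = pmin(uraw, cfg$uMax), s = sigmoid(zs),
       t = rowSoftmax(zt),
       cache = list(zp = zp, zu = zu, zs = zs, zt = zt, uraw = uraw))
}

#' Task heads: interaction, uncertainty, binding strength, type
#'
#' Maps the fused representation to the four per-pair outputs: interaction
#' probability `p = sigmoid(.)`, uncertainty `u = min(softplus(.), uMax)`,
#' binding strength `s = sigmoid(.)`, and a softmax distribution over the
#' C interaction-type classes.
#'
#' @param hFused fused representation (batch x hiddenDim).
#' @param model a [QuadNetModel-class].
#' @return list with vectors `p`, `u`, `s` and matrix `t` (batch x C).
#' @export
taskHeads <- function(hFused, model) {
  r <- headsForwardCore(hFused, modelParams(model), modelConfig(model))
  r[c("p", "u", "s", "t")]
}

## ---- full forward ----

quadnetForwardCore <- function(params, bundle, cfg, training = FALSE) {
  sc <- list()
  streams <- list()
  inputs <- list(s1 = bundle$x1, s2 = bundle$x2, sint = bundle$xInt,
                 sdiff = bundle$xDiff)
  outName <- c(s1 = "h1", s2 = "h2", sint = "hint", sdiff = "hdiff")
  for (s in streamNames) {
    r <- streamForwardCore(inputs[[s]], params, s, cfg, training = training)
    sc[[s]] <- r$cache
    streams[[outName[[s]]]] <- r$out
  }
  cr <- crossForwardCore(streams, params, cfg)
  fu <- fusionForwardCore(cr$finals, params)
  hd <- headsForwardCore(fu$hf, params, cfg)
  list(outputs = list(p = hd$p, u = hd$u, s = hd$s, t = hd$t),
       hFused = fu$hf,
       cache = list(streams = sc, streamOut = streams, cross = cr$caches,
                    finals = cr$finals, fusion = fu$cache, heads = hd$cache))
}

#' Full forward pass of the quad-stream network
#'
#' Runs the four attention streams, the cross-attention exchange, fusion,
#' and the task heads on an assembled feature bundle. Deterministic when
#' `training = FALSE` (dropout off).
#'
#' @param model a [QuadNetModel-class].
#' @param bundle a `FeatureBundle` from [assembleFeatures()] (or any list
#'   with matrices `x1`, `x2`, `xInt`, `xDiff`).
#' @param training if TRUE, dropout is active.
#' @return list with vectors `p`, `u`, `s` and matrix `t`.
#' @export
quadnetForward <- function(model, bundle, training = FALSE) {
  cfg <- modelConfig(model)
  if (ncol(bundle$x1) != cfg$inputDim) {
    stopf("bundle dimensionality (%d) does not match model inputDim (%d)",
          ncol(bundle$x1), cfg$inputDim)
  }
  quadnetForwardCore(modelParams(model), bundle, cfg, training = training)$outputs
}
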