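# The attention machinery: oracle equivalence, normalization, gating,
# cross-attention symmetry, fusion, heads, and gradient correctness.

test_that("multi-head attention matches the naive loop oracle", {
  cfg <- tinyCfg(hiddenDim = 12L, nTokens = 3L, numHeads = 2L)  # dK = 2
  model <- tinyModel(cfg, seed = 5)
  W <- attnWeights(model, "s1.attn")
  set.seed(5)
  X <- matrix(rnorm(7 * 12), 7)
  Y <- matrix(rnorm(7 * 12), 7)
  expect_equal(multiHeadAttention(X, X, W, cfg), naiveMHA(X, X, W, cfg),
               tolerance = 1e-6)
  # cross-attention (distinct key/value source) agrees too
  expect_equal(multiHeadAttention(X, Y, W, cfg), naiveMHA(X, Y, W, cfg),
               tolerance = 1e-6)
})

test_that("attention probability rows sum to 1", {
  cfg <- tinyCfg(hiddenDim = 8L, nTokens = 4L, numHeads = 2L)
  model <- tinyModel(cfg, seed = 6)
  W <- attnWeights(model, "sint.attn")
  set.seed(6)
  X <- matrix(rnorm(5 * 8), 5)
  r <- multiHeadAttention(X, X, W, cfg, returnWeights = TRUE)
  for (i in seq_along(r$weights)) {
    total <- Reduce(`+`, r$weights[[i]])
    expect_equal(total, matrix(1, 5, cfg$numHeads), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a single token degenerates attention to W_v W_o", {
  cfg <- tinyCfg(hiddenDim = 8L, nTokens = 1L, numHeads = 2L)
  model <- tinyModel(cfg, seed = 7)
  W <- attnWeights(model, "s2.attn")
  set.seed(7)
  X <- matrix(rnorm(4 * 8), 4)
  expect_equal(multiHeadAttention(X, X, W, cfg), X %*% W$Wv %*% W$Wo,
               tolerance = 1e-12)
})

test_that("attention block: output shape, zero-gate identity, batch independence", {
  cfg <- tinyCfg(inputDim = 5L, hiddenDim = 8L)
  model <- tinyModel(cfg, seed = 8)
  set.seed(8)
  x <- matrix(rnorm(6 * 5), 6)
  out <- attentionBlockForward(x, model, "s1")
  expect_identical(dim(out), c(6L, 8L))
  # alpha = 0 at init: the attention branch is bitwise inert
  sc <- quadnet:::streamForwardCore(x, modelParams(model), "s1",
                                    modelConfig(model))
  expect_identical(sc$cache$hAttn, sc$cache$h)
  # duplicated rows give duplicated outputs: no cross-example mixing
  x2 <- rbind(x[1, ], x)
  out2 <- attentionBlockForward(x2, model, "s1")
  expect_equal(out2[1, ], out2[2, ], tolerance = 1e-12)
  expect_equal(out2[-1, ], out, tolerance = 1e-12)
  expect_error(attentionBlockForward(x[, 1:3], model, "s1"), "expects")
})

test_that("zeroed cross-attention output projections leave streams unchanged", {
  cfg <- tinyCfg()
  model <- tinyModel(cfg, seed = 9)
  p <- modelParams(model)
  for (cn in c("c1", "c2", "cint", "cdiff")) {
    p[[paste0(cn, ".Wo")]] <- p[[paste0(cn, ".Wo")]] * 0
  }
  model0 <- withParams(model, p)
  set.seed(9)
  streams <- list(h1 = matrix(rnorm(3 * 8), 3), h2 = matrix(rnorm(3 * 8), 3),
                  hint = matrix(rnorm(3 * 8), 3), hdiff = matrix(rnorm(3 * 8), 3))
  finals <- crossAttentionExchange(streams, model0)
  expect_equal(finals$h1, streams$h1, tolerance = 1e-15)
  expect_equal(finals$hdiff, streams$hdiff, tolerance = 1e-15)
  expect_error(crossAttentionExchange(streams[c("h1", "h2")], model0),
               "missing stream")
})

test_that("tied protein-stream weights make the exchange swap-equivariant", {
  cfg <- tinyCfg(inputDim = 5L)
  model <- tinyModel(cfg, seed = 10)
  p <- modelParams(model)
  for (suf in c("proj.W", "proj.b", "ln1.g", "ln1.b", "attn.Wq", "attn.Wk",
                "attn.Wv", "attn.Wo", "alpha", "ln2.g", "ln2.b",
                "ffn.W1", "ffn.b1", "ffn.W2", "ffn.b2")) {
    p[[paste0("s2.", suf)]] <- p[[paste0("s1.", suf)]]
  }
  for (suf in c("Wq", "Wk", "Wv", "Wo")) {
    p[[paste0("c2.", suf)]] <- p[[paste0("c1.", suf)]]
  }
  tied <- withParams(model, p)
  set.seed(10)
  x1 <- matrix(rnorm(4 * 5), 4); x2 <- matrix(rnorm(4 * 5), 4)
  run <- function(a, b) {
    streams <- list(h1 = attentionBlockForward(a, tied, "s1"),
                    h2 = attentionBlockForward(b, tied, "s2"),
                    hint = attentionBlockForward(a * b, tied, "sint"),
                    hdiff = attentionBlockForward(abs(a - b), tied, "sdiff"))
    crossAttentionExchange(streams, tied)
  }
  fwd <- run(x1, x2)
  swp <- run(x2, x1)
  expect_equal(swp$h1, fwd$h2, tolerance = 1e-12)
  expect_equal(swp$h2, fwd$h1, tolerance = 1e-12)
  expect_equal(swp$hint, fwd$hint, tolerance = 1e-12)
  expect_equal(swp$hdiff, fwd$hdiff, tolerance = 1e-12)
})

test_that("fusion maps 4 streams to hiddenDim and is order-sensitive", {
  cfg <- tinyCfg()
  model <- tinyModel(cfg, seed = 11)
  set.seed(11)
  streams <- list(h1 = matrix(rnorm(3 * 8), 3), h2 = matrix(rnorm(3 * 8), 3),
                  hint = matrix(rnorm(3 * 8), 3), hdiff = matrix(rnorm(3 * 8), 3))
  hf <- quadFusion(streams, model)
  expect_identical(dim(hf), c(3L, 8L))
  # all-zero streams propagate only the biases: constant rows
  z <- lapply(streams, function(m) m * 0)
  hz <- quadFusion(z, model)
  expect_equal(hz[1, ], hz[2, ], tolerance = 1e-15)
  p <- modelParams(model)
  manual <- quadnet:::gelu(drop(
    quadnet:::gelu(p[["fusion.b1"]]) %*% p[["fusion.W2"]]) + p[["fusion.b2"]])
  expect_equal(hz[1, ], manual, tolerance = 1e-12)
  # permuting stream order changes the output
  perm <- quadFusion(list(h1 = streams$h2, h2 = streams$h1,
                          hint = streams$hint, hdiff = streams$hdiff), model)
  expect_gt(max(abs(perm - hf)), 1e-6)
})

test_that("task heads respect their activation ranges", {
  cfg <- tinyCfg(numTypes = 4L)
  model <- tinyModel(cfg, seed = 12)
  set.seed(12)
  hf <- matrix(rnorm(20 * 8, sd = 3), 20)
  out <- taskHeads(hf, model)
  expect_true(all(out$p > 0 & out$p < 1))
  expect_true(all(out$s > 0 & out$s < 1))
  expect_true(all(out$u >= 0 & out$u <= modelConfig(model)$uMax))
  expect_equal(rowSums(out$t), rep(1, 20), tolerance = 1e-6)
  # zeroed heads give the analytic neutral outputs
  p <- modelParams(model)
  for (nm in grep("^head\\.", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * 0
  out0 <- taskHeads(hf, withParams(model, p))
  expect_equal(out0$p, rep(0.5, 20))
  expect_equal(out0$s, rep(0.5, 20))
  expect_equal(out0$u, rep(log(2), 20))
  expect_equal(out0$t, matrix(0.25, 20, 4), ignore_attr = TRUE)
})

test_that("evaluation-phase forward is deterministic and batch-consistent", {
  cfg <- tinyCfg(inputDim = 6L)
  model <- tinyModel(cfg, seed = 13)
  bundle <- randomBundle(5, 6, seed = 13)
  o1 <- quadnetForward(model, bundle)
  o2 <- quadnetForward(model, bundle)
  expect_identical(o1, o2)
  # a singleton batch reproduces the corresponding row of the full batch
  single <- lapply(bundle[1:4], function(m) m[3, , drop = FALSE])
  oS <- quadnetForward(model, single)
  expect_equal(oS$p, o1$p[3], tolerance = 1e-12)
  expect_equal(drop(oS$t), o1$t[3, ], tolerance = 1e-12)
  expect_error(quadnetForward(model, randomBundle(5, 4, seed = 1)), "inputDim")
})

test_that("analytic gradients match central finite differences", {
  cfg <- tinyCfg()
  cfgU <- unclass(cfg)
  model <- tinyModel(cfg, seed = 3)
  params <- modelParams(model)
  # activate the attention gates so every parameter group is exercised
  for (s in c("s1", "s2", "sint", "sdiff")) params[[paste0(s, ".alpha")]] <- 0.7
  bundle <- randomBundle(4, 6, seed = 42)
  y <- c(1L, 0L, 1L, 0L)
  w <- lossWeights(1, 0.3, 0.5, 0.2)
  fw0 <- quadnet:::quadnetForwardCore(params, bundle, cfgU, training = FALSE)
  sFrozen <- bindingStrengthTarget(fw0$outputs$p, y)
  lossAt <- function(p) {
    o <- quadnet:::quadnetForwardCore(p, bundle, cfgU, training = FALSE)$outputs
    w$lambda1 * interactionLoss(o$p, y) +
      w$lambda2 * uncertaintyLoss(o$u, o$p, y) +
      w$lambda3 * bindingLoss(o$s, sFrozen) +  # stop-gradient target held fixed
      w$lambda4 * typeLoss(o$t)
  }
  dZ <- quadnet:::lossHeadGradients(fw0$outputs, fw0$cache$heads, y, w, cfgU)
  g <- quadnet:::quadnetBackwardCore(params, fw0$cache, dZ, cfgU)
  eps <- 1e-6
  set.seed(99)
  for (nm in names(params)) {
    pv <- params[[nm]]
    idx <- if (length(pv) > 4) sample(length(pv), 4) else seq_along(pv)
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      relErr <- abs(g[[nm]][i] - num) / max(1e-6, abs(num), abs(g[[nm]][i]))
      expect_lt(relErr, 1e-4, label = sprintf("grad %s[%d] rel. error", nm, i))
    }
  }
  # gradient reaches every parameter group
  groups <- unique(sub("\\.[^.]+$", "", names(g)))
  for (gr in groups) {
    nms <- grep(paste0("^", gr, "\\."), names(g), value = TRUE)
    if (!length(nms)) nms <- gr
    expect_gt(sum(vapply(g[nms], function(m) sum(abs(m)), numeric(1))), 0)
  }
})
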