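# Presets, grid search space, metrics/AUC, training determinism and
# capacity.

test_that("presets reproduce the published optimal configurations", {
  b <- presetConfig("table1-balanced")
  expect_identical(b$optimizer, "adamw")
  expect_equal(b$learningRate, 5e-4)
  expect_equal(b$weightDecay, 1e-4)
  expect_identical(b$scheduler, "plateau")
  expect_identical(b$batchSize, 128L)
  o <- presetConfig("table1-oversampled")
  expect_identical(o$optimizer, "rmsprop")
  expect_equal(o$learningRate, 1e-4)
  expect_equal(o$weightDecay, 1e-5)
  expect_identical(o$scheduler, "step")
  expect_identical(o$batchSize, 256L)
  cons <- presetConfig("conservative")
  expect_equal(cons$learningRate, 5e-4)
  expect_identical(cons$optimizer, "adamw")
  expect_error(presetConfig("nonsense"), "valid names")
})

test_that("the grid enumerates 432 configurations from the printed sets", {
  g <- gridSpace()
  expect_identical(length(g), 432L)
  lr <- vapply(g, `[[`, numeric(1), "learningRate")
  expect_setequal(unique(lr), c(1e-4, 5e-4, 1e-3, 2e-3))
  expect_setequal(unique(vapply(g, `[[`, numeric(1), "weightDecay")),
                  c(1e-5, 1e-4, 1e-3))
  expect_setequal(unique(vapply(g, `[[`, character(1), "optimizer")),
                  c("adam", "adamw", "rmsprop"))
  expect_setequal(unique(vapply(g, `[[`, character(1), "scheduler")),
                  c("plateau", "cosine", "step"))
  expect_setequal(unique(vapply(g, `[[`, integer(1), "batchSize")),
                  c(32L, 64L, 128L, 256L))
  # a budgeted subset is deterministic under a fixed seed
  s1 <- gridSpace(budget = 10, seed = 4)
  s2 <- gridSpace(budget = 10, seed = 4)
  expect_identical(s1, s2)
  expect_identical(length(s1), 10L)
})

test_that("metric identities hold on a hand-computed confusion fixture", {
  # 10 pairs: TP 4, FP 1, TN 3, FN 2
  rep <- quadnet:::metricsFromConfusion(tp = 4, fp = 1, tn = 3, fn = 2,
                                        auc = 0.875)
  expect_equal(rep$accuracy, 70)
  expect_equal(rep$precision, 80)
  expect_equal(rep$recall, 100 * 4 / 6)
  pr <- 0.8; rc <- 4 / 6
  expect_equal(rep$f1, 100 * 2 * pr * rc / (pr + rc))
  expect_equal(rep$auc_roc, 87.5)
})

test_that("rank AUC matches pROC and is ~50% under the null", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- rbinom(300, 1, 0.5)
  sc <- rnorm(300) + 0.8 * y
  ours <- aucFromScores(sc, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  # label-independent scores on 10,000 balanced pairs
  y0 <- rep(c(0, 1), 5000)
  auc0 <- aucFromScores(rnorm(10000), y0)
  expect_gte(auc0, 0.48)
  expect_lte(auc0, 0.52)
  expect_warning(aucFromScores(rnorm(5), rep(1, 5)), "single-class")
})

test_that("perfectly separable predictions give all five metrics at 100%", {
  bench <- smallBenchmark(nPairs = 60)
  df <- pairRecords(bench$pairs)
  # a surrogate scorer that reproduces the labels exactly
  rep <- quadnet:::metricsFromConfusion(
    tp = sum(df$label == 1), fp = 0, tn = sum(df$label == 0), fn = 0,
    auc = aucFromScores(df$label + 0.0, df$label))
  for (m in c("accuracy", "precision", "recall", "f1", "auc_roc")) {
    expect_equal(rep[[m]], 100)
  }
})

test_that("training is deterministic: same seed, same history and weights", {
  bench <- smallBenchmark(nPairs = 240)
  splits <- twoStageStratifiedSplit(bench$pairs,
                                    computeSplitSizes(length(bench$pairs)),
                                    seed = 3)
  cfg <- attentionConfig(inputDim = 8, hiddenDim = 16, numHeads = 4,
                         nTokens = 2, dropout = 0.1)
  tc <- trainingConfig(optimizer = "adam", learningRate = 1e-3,
                       weightDecay = 0, scheduler = "cosine", batchSize = 64,
                       maxEpochs = 4, patience = 10, seed = 21)
  run <- function() trainQuadNet(initQuadNet(cfg, seed = 2), bench$store,
                                 splits, tc)
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(modelParams(f1$model), modelParams(f2$model))
})

test_that("validation accuracy improves over the first epoch while training", {
  bench <- smallBenchmark(nProteins = 200, dim = 12, nPairs = 1200, seed = 17)
  splits <- twoStageStratifiedSplit(bench$pairs,
                                    computeSplitSizes(length(bench$pairs)),
                                    seed = 3)
  cfg <- attentionConfig(inputDim = 12, hiddenDim = 16, numHeads = 4,
                         nTokens = 2, dropout = 0)
  tc <- trainingConfig(optimizer = "adamw", learningRate = 2e-3,
                       weightDecay = 1e-4, scheduler = "plateau",
                       batchSize = 128, maxEpochs = 12, patience = 12,
                       seed = 5, augmentation = augmentationSpec(enabled = FALSE))
  fit <- trainQuadNet(initQuadNet(cfg, seed = 4), bench$store, splits, tc)
  expect_gt(max(fit$history$val_accuracy), fit$history$val_accuracy[1])
  # best-epoch pointer matches the maximum of the recorded history
  expect_equal(max(fit$history$val_accuracy),
               fit$history$val_accuracy[fit$bestEpoch])
})

test_that("the model can memorize 512 random pairs (capacity check)", {
  set.seed(51)
  n <- 64
  ids <- sprintf("P%06d", seq_len(n))
  X <- matrix(rnorm(n * 16), n, dimnames = list(ids, NULL))
  store <- EmbeddingStore(X)
  ia <- sample(ids, 512, replace = TRUE)
  ib <- sample(ids, 512, replace = TRUE)
  keep <- ia != ib
  df <- data.frame(protein_a = pmin(ia, ib)[keep], protein_b = pmax(ia, ib)[keep],
                   label = rbinom(sum(keep), 1, 0.5))
  df <- df[!duplicated(paste(df$protein_a, df$protein_b)), ]
  pairs <- PairTable(df)
  cfg <- attentionConfig(inputDim = 16, hiddenDim = 64, numHeads = 8,
                         nTokens = 8, dropout = 0)
  model <- initQuadNet(cfg, seed = 6)
  scaler <- fitRobustScaler(X)
  params <- modelParams(model)
  cfgU <- modelConfig(model)
  Z <- transformRobust(X, scaler); rownames(Z) <- ids
  iA <- match(df$protein_a, ids); iB <- match(df$protein_b, ids)
  y <- df$label
  w <- lossWeights()
  tc <- trainingConfig(optimizer = "adam", learningRate = 2e-3,
                       weightDecay = 0, scheduler = "cosine",
                       batchSize = 128, maxEpochs = 200, patience = 200,
                       seed = 9)
  opt <- quadnet:::optimizerInit(params)
  set.seed(9)
  acc <- 0
  for (epoch in seq_len(200)) {
    ord <- sample.int(length(y))
    for (start in seq(1, length(y), by = 128)) {
      idx <- ord[start:min(start + 127, length(y))]
      x1 <- Z[iA[idx], , drop = FALSE]; x2 <- Z[iB[idx], , drop = FALSE]
      bundle <- list(x1 = x1, x2 = x2, xInt = x1 * x2, xDiff = abs(x1 - x2))
      fw <- quadnet:::quadnetForwardCore(params, bundle, cfgU, training = TRUE)
      dZ <- quadnet:::lossHeadGradients(fw$outputs, fw$cache$heads, y[idx], w, cfgU)
      g <- quadnet:::quadnetBackwardCore(params, fw$cache, dZ, cfgU)
      st <- quadnet:::optimizerStep(params, g, opt, tc, 2e-3)
      params <- st$params; opt <- st$state
    }
    p <- quadnet:::forwardProbs(params, cfgU, Z, iA, iB)
    acc <- mean(predictedLabel(p) == y)
    if (acc > 0.99) break
  }
  expect_gt(acc, 0.99)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  bench <- smallBenchmark(nPairs = 120)
  splits <- twoStageStratifiedSplit(bench$pairs,
                                    computeSplitSizes(length(bench$pairs)),
                                    seed = 3)
  cfg <- attentionConfig(inputDim = 8, hiddenDim = 8, numHeads = 2,
                         nTokens = 2, dropout = 0)
  # a step size huge enough to overflow the activations into NaN
  tc <- trainingConfig(optimizer = "adam", learningRate = 1e200,
                       weightDecay = 0, scheduler = "step", batchSize = 32,
                       maxEpochs = 4, patience = 4, seed = 1)
  expect_error(trainQuadNet(initQuadNet(cfg, seed = 1), bench$store, splits, tc),
               "diverged|non-finite")
})

test_that("YAML config files mirror trainingConfig", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("optimizer: rmsprop", "learning_rate: 2.0e-3",
               "weight_decay: 1.0e-5", "scheduler: step", "batch_size: 64",
               "max_epochs: 7", "seed: 3",
               "loss_weights: [1.0, 0.2, 0.3, 0.4]",
               "augmentation_sigma: 0.05"), path)
  tc <- readTrainingConfig(path)
  expect_identical(tc$optimizer, "rmsprop")
  expect_equal(tc$learningRate, 2e-3)
  expect_identical(tc$batchSize, 64L)
  expect_identical(tc$maxEpochs, 7L)
  expect_equal(tc$weights$lambda3, 0.3)
  expect_equal(tc$augmentation$sigma, 0.05)
})
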