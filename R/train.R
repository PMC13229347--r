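## Training loop with Adam / AdamW / RMSprop, the three learning-rate
## schedules, preset and grid hyperparameter configurations, early
## stopping, and best-validation-accuracy model selection.

#' Training configuration
#'
#' @param optimizer `"adam"`, `"adamw"` (decoupled weight decay) or
#'   `"rmsprop"`.
#' @param learningRate initial learning rate (> 0).
#' @param weightDecay L2 / decoupled decay coefficient.
#' @param scheduler `"plateau"` (halve on validation-accuracy plateau,
#'   patience 5), `"cosine"` (anneal to ~0 over `maxEpochs`) or `"step"`
#'   (halve every 10 epochs).
#' @param batchSize mini-batch size.
#' @param maxEpochs maximum epochs (default 100).
#' @param patience early-stopping patience on validation accuracy
#'   (default 10).
#' @param seed seed controlling shuffling, dropout and augmentation.
#' @param weights a [lossWeights()].
#' @param augmentation an [augmentationSpec()] applied to training batches
#'   (NULL disables).
#' @param dropout overrides the model config dropout during training if
#'   not NULL.
#' @return list of class `TrainingConfig`.
#' @export
trainingConfig <- function(optimizer = c("adamw", "adam", "rmsprop"),
                           learningRate = 5e-4, weightDecay = 1e-4,
                           scheduler = c("plateau", "cosine", "step"),
                           batchSize = 128L, maxEpochs = 100L, patience = 10L,
                           seed = 1L, weights = lossWeights(),
                           augmentation = augmentationSpec(), dropout = NULL) {
  optimizer <- match.arg(optimizer)
  scheduler <- match.arg(scheduler)
  if (learningRate <= 0) stopf("learningRate must be positive")
  structure(list(optimizer = optimizer, learningRate = learningRate,
                 weightDecay = weightDecay, scheduler = scheduler,
                 batchSize = assertCount(batchSize, "batchSize"),
                 maxEpochs = assertCount(maxEpochs, "maxEpochs"),
                 patience = assertCount(patience, "patience"),
                 seed = assertCount(seed, "seed", min = 0L),
                 weights = weights, augmentation = augmentation,
                 dropout = dropout),
            class = "TrainingConfig")
}

#' Preset training configurations
#'
#' The three pre-configured settings explored during hyperparameter search
#' (conservative / aggressive / balanced) plus the two best-performing
#' configurations found for the balanced and oversampled pair datasets.
#'
#' @param name one of `"conservative"`, `"aggressive"`, `"balanced"`,
#'   `"table1-balanced"`, `"table1-oversampled"`.
#' @param ... overrides passed to [trainingConfig()] (e.g. `maxEpochs`).
#' @return a [trainingConfig()].
#' @export
presetConfig <- function(name, ...) {
  presets <- list(
    "conservative" = list(optimizer = "adamw", learningRate = 5e-4,
                          weightDecay = 1e-4, scheduler = "plateau"),
    "aggressive" = list(optimizer = "adam", learningRate = 1e-3,
                        weightDecay = 1e-3, scheduler = "cosine"),
    "balanced" = list(optimizer = "rmsprop", learningRate = 1e-4,
                      weightDecay = 1e-5, scheduler = "step"),
    "table1-balanced" = list(optimizer = "adamw", learningRate = 5e-4,
                             weightDecay = 1e-4, scheduler = "plateau",
                             batchSize = 128L),
    "table1-oversampled" = list(optimizer = "rmsprop", learningRate = 1e-4,
                                weightDecay = 1e-5, scheduler = "step",
                                batchSize = 256L)
  )
  if (!name %in% names(presets)) {
    stopf("unknown preset '%s'; valid names: %s", name,
          paste(names(presets), collapse = ", "))
  }
  do.call(trainingConfig, utils::modifyList(presets[[name]], list(...)))
}

#' Hyperparameter grid
#'
#' The full Cartesian search space: 4 learning rates (1e-4, 5e-4, 1e-3,
#' 2e-3) x 3 weight decays (1e-5, 1e-4, 1e-3) x 3 optimizers x 3
#' schedulers x 4 batch sizes (32, 64, 128, 256) = 432 configurations,
#' optionally subsampled to a seeded random budget.
#'
#' @param budget optional number of configurations to sample.
#' @param seed seed for the budgeted subsample.
#' @param ... overrides passed to every [trainingConfig()].
#' @return list of [trainingConfig()] objects.
#' @export
gridSpace <- function(budget = NULL, seed = 1L, ...) {
  grid <- expand.grid(learningRate = c(1e-4, 5e-4, 1e-3, 2e-3),
                      weightDecay = c(1e-5, 1e-4, 1e-3),
                      optimizer = c("adam", "adamw", "rmsprop"),
                      scheduler = c("plateau", "cosine", "step"),
                      batchSize = c(32L, 64L, 128L, 256L),
                      stringsAsFactors = FALSE)
  if (!is.null(budget)) {
    set.seed(seed)
    grid <- grid[sample.int(nrow(grid), assertCount(budget, "budget")), ,
                 drop = FALSE]
  }
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(trainingConfig, c(as.list(grid[i, ]), list(...)))
  })
}

#' Read a training configuration from a YAML file
#'
#' The file mirrors [trainingConfig()] fields (snake_case or camelCase
#' accepted), e.g.:
#'
#' ```yaml
#' optimizer: adamw
#' learning_rate: 5.0e-4
#' weight_decay: 1.0e-4
#' scheduler: plateau
#' batch_size: 128
#' max_epochs: 50
#' seed: 1
#' loss_weights: [1.0, 0.1, 0.1, 0.1]
#' augmentation_sigma: 0.02
#' ```
#'
#' @param path YAML file path.
#' @return a [trainingConfig()].
#' @export
readTrainingConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("the 'yaml' package is required to read config files")
  }
  y <- yaml::read_yaml(path)
  camel <- function(nm) gsub("_(\\w)", "\\U\\1", nm, perl = TRUE)
  names(y) <- camel(names(y))
  if (!is.null(y$lossWeights)) {
    y$weights <- do.call(lossWeights, as.list(as.numeric(y$lossWeights)))
    y$lossWeights <- NULL
  }
  if (!is.null(y$augmentationSigma)) {
    y$augmentation <- augmentationSpec(sigma = as.numeric(y$augmentationSigma))
    y$augmentationSigma <- NULL
  }
  do.call(trainingConfig, y)
}

## ---- optimizers (operate on flat named parameter lists) ----

optimizerInit <- function(params) {
  zeros <- lapply(params, function(x) x * 0)
  list(t = 0L, m = zeros, v = zeros)
}

optimizerStep <- function(params, grads, state, config, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rmsAlpha <- 0.99
  state$t <- state$t + 1L
  wd <- config$weightDecay
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (config$optimizer %in% c("adam", "rmsprop") && wd > 0) {
      g <- g + wd * params[[nm]]  # classic L2 regularization in the gradient
    }
    if (config$optimizer == "rmsprop") {
      state$v[[nm]] <- rmsAlpha * state$v[[nm]] + (1 - rmsAlpha) * g^2
      upd <- lr * g / (sqrt(state$v[[nm]]) + eps)
    } else {
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
      mhat <- state$m[[nm]] / (1 - b1^state$t)
      vhat <- state$v[[nm]] / (1 - b2^state$t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
    }
    if (config$optimizer == "adamw" && wd > 0) {
      upd <- upd + lr * wd * params[[nm]]  # decoupled decay
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

## ---- schedulers: return the lr for the coming epoch ----

schedulerInit <- function(config) {
  list(lr = config$learningRate, best = -Inf, bad = 0L)
}

schedulerStep <- function(sched, config, epoch, valMetric) {
  if (config$scheduler == "step") {
    if (epoch %% 10L == 0L) sched$lr <- sched$lr * 0.5
  } else if (config$scheduler == "cosine") {
    sched$lr <- config$learningRate *
      0.5 * (1 + cos(pi * epoch / config$maxEpochs))
  } else {  # plateau on validation accuracy, factor 0.5, patience 5
    if (valMetric > sched$best + 1e-12) {
      sched$best <- valMetric
      sched$bad <- 0L
    } else {
      sched$bad <- sched$bad + 1L
      if (sched$bad >= 5L) {
        sched$lr <- max(sched$lr * 0.5, 1e-6)
        sched$bad <- 0L
      }
    }
  }
  sched
}

## Predict interaction probabilities for a pair index set in mini-batches.
forwardProbs <- function(params, cfg, X, ia, ib, batchSize = 512L) {
  n <- length(ia)
  out <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    x1 <- X[ia[idx], , drop = FALSE]
    x2 <- X[ib[idx], , drop = FALSE]
    bundle <- list(x1 = x1, x2 = x2, xInt = x1 * x2, xDiff = abs(x1 - x2))
    out[idx] <- quadnetForwardCore(params, bundle, cfg, training = FALSE)$outputs$p
  }
  out
}

#' Train a quad-stream model on split pair data
#'
#' Fits the robust scaler on the embeddings of proteins occurring in
#' training pairs, then optimizes the weighted multi-task loss by
#' mini-batch gradient descent with the configured optimizer and schedule.
#' Gaussian augmentation (when enabled) perturbs the scaled training
#' embeddings with fresh noise every epoch. Validation accuracy is
#' monitored per epoch for the plateau schedule, early stopping, and
#' best-model selection. Fully deterministic given the config seed.
#'
#' @param model an initialized [QuadNetModel-class].
#' @param store an [EmbeddingStore-class] covering all split proteins.
#' @param splits a [DatasetSplits-class].
#' @param config a [trainingConfig()].
#' @param scaler optional pre-fitted [RobustScaler-class]; fitted on the
#'   training proteins when NULL.
#' @param verbose print per-epoch progress.
#' @return list with elements `model` (best-validation parameters),
#'   `history` (per-epoch data.frame: losses, lr, validation accuracy and
#'   AUC), `scaler`, and `bestEpoch`.
#' @export
trainQuadNet <- function(model, store, splits, config, scaler = NULL,
                         verbose = FALSE) {
  cfg <- modelConfig(model)
  if (!is.null(config$dropout)) cfg$dropout <- config$dropout
  params <- modelParams(model)
  trainDf <- pairRecords(trainSet(splits))
  valDf <- pairRecords(valSet(splits))
  if (!nrow(trainDf)) stopf("empty training split")
  if (is.null(scaler)) {
    trainProteins <- unique(c(trainDf$protein_a, trainDf$protein_b))
    scaler <- fitRobustScaler(embeddingMatrix(store)[trainProteins, , drop = FALSE])
  }
  X <- transformRobust(embeddingMatrix(store), scaler)
  rownames(X) <- proteinIds(store)
  rowIdx <- stats::setNames(seq_len(nrow(X)), rownames(X))
  ia <- rowIdx[trainDf$protein_a]; ib <- rowIdx[trainDf$protein_b]
  y <- trainDf$label
  va <- rowIdx[valDf$protein_a]; vb <- rowIdx[valDf$protein_b]
  vy <- valDf$label
  n <- length(y)
  sigma <- if (!is.null(config$augmentation) && config$augmentation$enabled) {
    config$augmentation$sigma
  } else 0
  set.seed(deriveSeed(config$seed, "train"))
  optState <- optimizerInit(params)
  sched <- schedulerInit(config)
  history <- vector("list", config$maxEpochs)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  badEpochs <- 0L
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(n)
    comp <- c(L_interact = 0, L_uncertainty = 0, L_binding = 0, L_type = 0,
              L_total = 0)
    nBatches <- 0L
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      x1 <- X[ia[idx], , drop = FALSE]
      x2 <- X[ib[idx], , drop = FALSE]
      if (sigma > 0) {
        x1 <- x1 + stats::rnorm(length(x1), sd = sigma)
        x2 <- x2 + stats::rnorm(length(x2), sd = sigma)
      }
      bundle <- list(x1 = x1, x2 = x2, xInt = x1 * x2, xDiff = abs(x1 - x2))
      fw <- quadnetForwardCore(params, bundle, cfg, training = TRUE)
      if (!all(is.finite(fw$outputs$p))) {
        stopf("training diverged at epoch %d (non-finite forward pass)", epoch)
      }
      lb <- totalLoss(fw$outputs$p, fw$outputs$u, fw$outputs$s, fw$outputs$t,
                      y[idx], weights = config$weights)
      if (!is.finite(lb$L_total)) {
        stopf("training diverged at epoch %d (non-finite loss)", epoch)
      }
      dZ <- lossHeadGradients(fw$outputs, fw$cache$heads, y[idx],
                              config$weights, cfg)
      grads <- quadnetBackwardCore(params, fw$cache, dZ, cfg)
      stepRes <- optimizerStep(params, grads, optState, config, sched$lr)
      params <- stepRes$params
      optState <- stepRes$state
      comp <- comp + c(lb$L_interact, lb$L_uncertainty, lb$L_binding,
                       lb$L_type, lb$L_total)
      nBatches <- nBatches + 1L
    }
    comp <- comp / nBatches
    vp <- forwardProbs(params, cfg, X, va, vb)
    valAcc <- mean(predictedLabel(vp) == vy)
    valAuc <- aucFromScores(vp, vy)
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = sched$lr,
      L_interact = comp[[1]], L_uncertainty = comp[[2]],
      L_binding = comp[[3]], L_type = comp[[4]], L_total = comp[[5]],
      val_accuracy = valAcc, val_auc = if (is.na(valAuc)) NA_real_ else valAuc)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val acc %.4f",
                      epoch, sched$lr, comp[[5]], valAcc))
    }
    if (valAcc > best$acc + 1e-12) {
      best <- list(acc = valAcc, params = params, epoch = epoch)
      badEpochs <- 0L
    } else {
      badEpochs <- badEpochs + 1L
    }
    if (badEpochs >= config$patience) break
    sched <- schedulerStep(sched, config, epoch, valAcc)
  }
  list(model = withParams(model, best$params),
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       scaler = scaler, bestEpoch = best$epoch)
}
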