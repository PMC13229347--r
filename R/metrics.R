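## Evaluation: confusion counts, the five classification metrics, and
## per-pair prediction tables.

#' Area under the ROC curve from scores
#'
#' Tie-aware rank statistic (equivalent to the normalized Mann-Whitney U):
#' `AUC = (sum of positive-score ranks - n1 (n1 + 1) / 2) / (n1 n0)` with
#' average ranks for ties.
#'
#' @param scores numeric prediction scores.
#' @param y 0/1 labels.
#' @return AUC in \[0, 1\], or NA (with a warning) when only one class is
#'   present.
#' @export
aucFromScores <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined for a single-class evaluation set")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metricsFromConfusion <- function(tp, fp, tn, fn, auc = NA_real_) {
  n <- tp + fp + tn + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(
    accuracy = 100 * (tp + tn) / n,
    precision = 100 * precision, recall = 100 * recall, f1 = 100 * f1,
    auc_roc = 100 * auc,
    TP = tp, FP = fp, TN = tn, FN = fn, n = n),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(paste0(
    "Metrics on %d pairs:\n",
    "  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  AUC-ROC %.2f%%\n",
    "  confusion: TP %d  FP %d  TN %d  FN %d\n"),
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc_roc,
    x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Evaluate a trained model on labeled pairs
#'
#' Computes interaction probabilities for every pair, thresholds at 0.5
#' for the confusion matrix, and reports accuracy, precision, recall, F1
#' and AUC-ROC (all as percentages) together with the confusion counts.
#'
#' @param model a trained [QuadNetModel-class].
#' @param pairs a labeled [PairTable-class].
#' @param store an [EmbeddingStore-class].
#' @param scaler the [RobustScaler-class] used in training.
#' @return a `MetricsReport` list (printable).
#' @export
evaluateModel <- function(model, pairs, store, scaler) {
  preds <- predictPairs(model, pairs, store, scaler)
  df <- pairRecords(pairs)
  y <- df$label
  yhat <- predictedLabel(preds$p_interact)
  metricsFromConfusion(tp = sum(yhat == 1 & y == 1),
                       fp = sum(yhat == 1 & y == 0),
                       tn = sum(yhat == 0 & y == 0),
                       fn = sum(yhat == 0 & y == 1),
                       auc = suppressWarnings(aucFromScores(preds$p_interact, y)))
}

#' Per-pair predictions of all four task heads
#'
#' @param model a trained [QuadNetModel-class].
#' @param pairs a [PairTable-class] or data.frame with `protein_a`,
#'   `protein_b`.
#' @param store an [EmbeddingStore-class].
#' @param scaler the fitted [RobustScaler-class].
#' @param batchSize forward-pass batch size.
#' @return data.frame: `protein_a`, `protein_b`, `p_interact`, `u`, `s`,
#'   `argmax_type`.
#' @export
predictPairs <- function(model, pairs, store, scaler, batchSize = 512L) {
  df <- if (inherits(pairs, "PairTable")) pairRecords(pairs) else pairs
  cfg <- modelConfig(model)
  params <- modelParams(model)
  X <- transformRobust(embeddingMatrix(store), scaler)
  rownames(X) <- proteinIds(store)
  missing <- setdiff(unique(c(df$protein_a, df$protein_b)), rownames(X))
  if (length(missing)) {
    stopf("identifier(s) absent from store: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  n <- nrow(df)
  p <- u <- s <- numeric(n)
  tmax <- integer(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    x1 <- X[df$protein_a[idx], , drop = FALSE]
    x2 <- X[df$protein_b[idx], , drop = FALSE]
    bundle <- list(x1 = x1, x2 = x2, xInt = x1 * x2, xDiff = abs(x1 - x2))
    out <- quadnetForwardCore(params, bundle, cfg, training = FALSE)$outputs
    p[idx] <- out$p; u[idx] <- out$u; s[idx] <- out$s
    tmax[idx] <- max.col(out$t, ties.method = "first")
  }
  data.frame(protein_a = df$protein_a, protein_b = df$protein_b,
             p_interact = p, u = u, s = s, argmax_type = tmax,
             stringsAsFactors = FALSE)
}
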