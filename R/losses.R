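## The four task losses and their weighted combination. Each component has
## a closed-form gradient with respect to its head pre-activation; these
## feed quadnetBackwardCore() during training.

probEps <- 1e-7

#' Loss weights for the multi-task objective
#'
#' The total loss is `lambda1 * L_interact + lambda2 * L_uncertainty +
#' lambda3 * L_binding + lambda4 * L_type`. Defaults keep the primary
#' interaction task dominant with the three auxiliary heads acting as
#' regularizers.
#'
#' @param lambda1,lambda2,lambda3,lambda4 nonnegative component weights.
#' @return list of class `LossWeights`.
#' @export
lossWeights <- function(lambda1 = 1.0, lambda2 = 0.1, lambda3 = 0.1,
                        lambda4 = 0.1) {
  w <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(w < 0) || !any(w > 0)) {
    stopf("loss weights must be nonnegative with at least one positive")
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4), class = "LossWeights")
}

#' Binary cross-entropy interaction loss
#'
#' Mean binary cross-entropy of predicted interaction probabilities against
#' 0/1 labels; probabilities are clipped to `[1e-7, 1 - 1e-7]` before the
#' logarithms.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y labels in 0/1, same length.
#' @return scalar loss.
#' @examples
#' interactionLoss(0.5, 1)  # log(2)
#' @export
interactionLoss <- function(p, y) {
  if (length(p) != length(y)) stopf("length mismatch: %d vs %d", length(p), length(y))
  pc <- pmin(pmax(p, probEps), 1 - probEps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Hard label from a predicted probability
#'
#' `1` iff `p > 0.5` (strict inequality: `p = 0.5` maps to 0).
#'
#' @param p probabilities in \[0, 1\].
#' @return integer 0/1 vector.
#' @export
predictedLabel <- function(p) as.integer(p > 0.5)

#' Uncertainty loss
#'
#' Mean of `+u` over correctly classified pairs and `-u` over
#' misclassified pairs (classification by [predictedLabel()]), pushing
#' uncertainty toward 0 on correct predictions and toward the cap on
#' incorrect ones. Uncapped, the objective is unbounded below on a
#' persistently wrong prediction; the model's softplus head is therefore
#' capped at `uMax` upstream.
#'
#' @param u nonnegative uncertainty values.
#' @param p predicted probabilities.
#' @param y 0/1 labels.
#' @return scalar loss (sign mixed).
#' @export
uncertaintyLoss <- function(u, p, y) {
  if (any(u < 0)) stopf("uncertainty values must be nonnegative")
  yhat <- predictedLabel(p)
  mean(ifelse(yhat == y, u, -u))
}

#' Confidence-derived binding-strength target
#'
#' `s_target = 2 * |p - 0.5| * y`: for interacting pairs, the rescaled
#' distance of the predicted probability from chance; zero for
#' non-interacting pairs. Treated as a constant — no gradient flows through
#' `p` into the target (a target that moved with the prediction would
#' collapse the regression).
#'
#' @param p predicted probabilities.
#' @param y 0/1 labels.
#' @return targets in \[0, 1\].
#' @export
bindingStrengthTarget <- function(p, y) 2 * abs(p - 0.5) * y

#' Binding-strength loss
#'
#' Mean squared error between the predicted binding strength and its
#' confidence-derived target.
#'
#' @param s predicted strengths in \[0, 1\].
#' @param sTarget targets from [bindingStrengthTarget()].
#' @return scalar loss.
#' @export
bindingLoss <- function(s, sTarget) {
  if (length(s) != length(sTarget)) {
    stopf("length mismatch: %d vs %d", length(s), length(sTarget))
  }
  mean((s - sTarget)^2)
}

#' Interaction-type loss
#'
#' With known type labels: mean cross-entropy of the softmax type
#' distributions. Without labels (the usual case — interaction databases
#' rarely annotate types): mean KL divergence of each distribution from the
#' uniform distribution over the C classes, a regularizer that keeps the
#' head from collapsing.
#'
#' @param t matrix (batch x C) of type distributions (rows on the simplex).
#' @param yType optional integer class labels in 1..C.
#' @param C number of classes (default `ncol(t)`).
#' @return scalar loss.
#' @export
typeLoss <- function(t, yType = NULL, C = ncol(t)) {
  t <- as.matrix(t)
  if (any(abs(rowSums(t) - 1) > 1e-5)) {
    stopf("type distributions must sum to 1 per row")
  }
  tc <- pmax(t, probEps)
  if (is.null(yType)) {
    mean(rowSums(t * log(tc * C)))
  } else {
    -mean(log(tc[cbind(seq_len(nrow(t)), yType)]))
  }
}

#' Weighted multi-task total loss
#'
#' Combines the four components with the given weights and returns the
#' full breakdown.
#'
#' @param p,u,s,t head outputs (see [taskHeads()]).
#' @param y 0/1 interaction labels.
#' @param weights a [lossWeights()].
#' @param yType optional type labels (switches the type loss to
#'   cross-entropy).
#' @return list of class `LossBreakdown` with `L_interact`,
#'   `L_uncertainty`, `L_binding`, `L_type`, `L_total`, the batch size `N`,
#'   the binding targets `sTarget` and hard labels `yhat`.
#' @export
totalLoss <- function(p, u, s, t, y, weights = lossWeights(), yType = NULL) {
  sTarget <- bindingStrengthTarget(p, y)
  li <- interactionLoss(p, y)
  lu <- uncertaintyLoss(u, p, y)
  lb <- bindingLoss(s, sTarget)
  lt <- typeLoss(t, yType = yType)
  structure(list(
    L_interact = li, L_uncertainty = lu, L_binding = lb, L_type = lt,
    L_total = weights$lambda1 * li + weights$lambda2 * lu +
      weights$lambda3 * lb + weights$lambda4 * lt,
    N = length(y), sTarget = sTarget, yhat = predictedLabel(p)),
    class = "LossBreakdown")
}

## Gradients of the weighted total loss with respect to the four head
## pre-activations. `heads` is the cache from headsForwardCore(); uMax
## masks the uncertainty gradient where the cap is active.
lossHeadGradients <- function(out, headsCache, y, weights, cfg) {
  N <- length(y)
  p <- out$p; u <- out$u; s <- out$s; t <- out$t
  ## interaction: d BCE / d zp = (p - y) / N
  dzp <- weights$lambda1 * (p - y) / N
  ## uncertainty: d/du = +-1/N, du/dzu = sigmoid(zu) where uncapped
  sign <- ifelse(predictedLabel(p) == y, 1, -1)
  capped <- headsCache$uraw >= cfg$uMax
  dzu <- weights$lambda2 * sign * sigmoid(headsCache$zu) * (1 - capped) / N
  ## binding: d MSE / d zs = 2 (s - s_target) s (1 - s) / N (s_target constant)
  sTarget <- bindingStrengthTarget(p, y)
  dzs <- weights$lambda3 * 2 * (s - sTarget) * s * (1 - s) / N
  ## type (KL-to-uniform): d/d zt_k = t_k (log t_k - sum_c t_c log t_c) / N
  tc <- pmax(t, probEps)
  lt <- log(tc)
  dzt <- weights$lambda4 * t * (lt - rowSums(t * lt)) / N
  list(dzp = dzp, dzu = dzu, dzs = dzs, dzt = dzt)
}
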