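## Robust median/IQR scaling of embedding matrices, pair feature
## construction (element-wise product and absolute difference), and
## Gaussian-noise augmentation.

#' Fit a robust median/IQR scaler
#'
#' Computes per-dimension median and interquartile range (Q3 - Q1) of a
#' training embedding matrix under the linear-interpolation (type 7)
#' quantile convention. Dimensions whose IQR falls below `iqrFloor` are
#' degenerate (near-constant); their scale is set to 1 so the transform
#' centers but does not amplify them. Median/IQR are preferred over
#' mean/sd because language-model embeddings are heavy-tailed and contain
#' outliers that would dominate moment-based statistics.
#'
#' @param X numeric training matrix (>= 2 rows).
#' @param iqrFloor degenerate-dispersion threshold (default 1e-8).
#' @return A [RobustScaler-class].
#' @examples
#' sc <- fitRobustScaler(matrix(1:5, ncol = 1))
#' transformRobust(matrix(1:5, ncol = 1), sc)  # -1 -0.5 0 0.5 1
#' @export
fitRobustScaler <- function(X, iqrFloor = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 rows to fit a scaler, got %d", nrow(X))
  q <- apply(X, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
             names = FALSE, type = 7)
  iqr <- q[3L, ] - q[1L, ]
  if (any(iqr < 0)) stopf("negative IQR encountered; input is not ordered data")
  iqr[iqr < iqrFloor] <- 1
  new("RobustScaler", center = q[2L, ], scale = iqr,
      iqrFloor = iqrFloor, quantileType = 7L, fittedOn = matrixDigest(X))
}

#' Apply a fitted robust scaler
#'
#' Returns `(X - median) / IQR` element-wise per dimension. Applied to the
#' training matrix itself, each non-degenerate dimension has median 0 and
#' IQR 1.
#'
#' @param X numeric matrix (or vector treated as one row).
#' @param scaler a [RobustScaler-class].
#' @return scaled matrix of the same shape.
#' @export
transformRobust <- function(X, scaler) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  d <- length(scaler@center)
  if (ncol(X) != d) {
    stopf("dimension mismatch: X has %d columns, scaler was fitted on %d",
          ncol(X), d)
  }
  sweep(sweep(X, 2L, scaler@center, "-"), 2L, scaler@scale, "/")
}

#' Element-wise product feature of a protein pair
#'
#' `x1 * x2` per dimension: the synergistic-activation feature, large where
#' both proteins activate the same embedding dimension strongly. Symmetric
#' in its arguments.
#'
#' @param x1,x2 numeric vectors or matrices of equal shape.
#' @return element-wise product, same shape.
#' @export
interactionProduct <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stopf("length mismatch: %d vs %d", length(x1), length(x2))
  }
  x1 * x2
}

#' Absolute difference feature of a protein pair
#'
#' `|x1 - x2|` per dimension: the complementary-activation feature,
#' quantifying contrast between the two embeddings. Symmetric and
#' nonnegative.
#'
#' @inheritParams interactionProduct
#' @return element-wise absolute difference, same shape.
#' @export
absoluteDifference <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stopf("length mismatch: %d vs %d", length(x1), length(x2))
  }
  abs(x1 - x2)
}

#' Gaussian-noise augmentation specification
#'
#' @param sigma noise standard deviation (default 0.02, the value used on
#'   scaled embeddings during training).
#' @param enabled whether augmentation is active (training phase only).
#' @return list of class `AugmentationSpec`.
#' @export
augmentationSpec <- function(sigma = 0.02, enabled = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stopf("'sigma' must be a single nonnegative number")
  }
  structure(list(sigma = sigma, enabled = isTRUE(enabled)),
            class = "AugmentationSpec")
}

#' Add isotropic Gaussian noise to an embedding
#'
#' `x + e` with `e ~ N(0, sigma^2 I)`, drawn fresh on every call (so
#' training re-perturbs each epoch). With `sigma = 0` (or a disabled spec)
#' the input is returned exactly.
#'
#' @param x numeric vector or matrix.
#' @param spec an [augmentationSpec()].
#' @return perturbed copy of `x`, same shape.
#' @export
augmentGaussian <- function(x, spec = augmentationSpec()) {
  if (!inherits(spec, "AugmentationSpec")) stopf("'spec' must be an augmentationSpec()")
  if (!spec$enabled || spec$sigma == 0) return(x)
  x + stats::rnorm(length(x), sd = spec$sigma)
}

#' Assemble the four model inputs for protein pairs
#'
#' Looks up both embedding vectors, applies the robust scaler, optionally
#' perturbs the scaled vectors with Gaussian noise (training phase only),
#' and derives the product and absolute-difference features from the
#' (possibly augmented) scaled vectors.
#'
#' @param pairs a [PairTable-class] or data.frame with `protein_a`,
#'   `protein_b`.
#' @param store an [EmbeddingStore-class] containing all referenced
#'   identifiers.
#' @param scaler a fitted [RobustScaler-class].
#' @param augmentation optional [augmentationSpec()]; NULL disables.
#' @return list of class `FeatureBundle` with matrices `x1`, `x2`, `xInt`,
#'   `xDiff` (rows = pairs) and the label vector `y` when present.
#' @export
assembleFeatures <- function(pairs, store, scaler, augmentation = NULL) {
  df <- if (inherits(pairs, "PairTable")) pairRecords(pairs) else pairs
  ids <- rownames(embeddingMatrix(store))
  missing <- setdiff(unique(c(df$protein_a, df$protein_b)), ids)
  if (length(missing)) {
    stopf("identifier(s) absent from store: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  X <- transformRobust(embeddingMatrix(store), scaler)
  rownames(X) <- ids
  x1 <- X[df$protein_a, , drop = FALSE]
  x2 <- X[df$protein_b, , drop = FALSE]
  if (!is.null(augmentation)) {
    x1 <- augmentGaussian(x1, augmentation)
    x2 <- augmentGaussian(x2, augmentation)
  }
  structure(list(x1 = x1, x2 = x2,
                 xInt = interactionProduct(x1, x2),
                 xDiff = absoluteDifference(x1, x2),
                 y = if ("label" %in% names(df)) as.integer(df$label) else NULL),
            class = "FeatureBundle")
}
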