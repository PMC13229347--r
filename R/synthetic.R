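#' Specification for the synthetic PPI benchmark generator
#'
#' Describes a synthetic embedding store plus a planted pairwise interaction
#' rule. Embedding coordinates are drawn from a scaled Student-t with
#' `tailDf` degrees of freedom, emulating the heavy-tailed, outlier-bearing
#' distributions of real protein language-model embeddings (the reason the
#' pipeline uses robust median/IQR scaling rather than z-scoring). Labels
#' come from a symmetric bilinear rule of rank `ruleRank` thresholded so the
#' positive rate is `posFrac`; `labelNoise` flips each planted label
#' independently.
#'
#' @param nProteins number of proteins (>= 2 unless only the store is used).
#' @param dim embedding dimensionality (1024 matches typical protein
#'   language-model output; reduce for tests).
#' @param tailDf degrees of freedom of the per-coordinate Student-t
#'   (default 3: heavy tails with finite variance).
#' @param ruleRank rank r of the planted bilinear matrix (default 4).
#' @param labelNoise probability in \[0, 0.5) of flipping a planted label.
#' @param posFrac target positive fraction in (0, 1).
#' @param offDiag mixing weight in \[0, 1) of the random (off-axis) component
#'   of each planted eigenvector; 0 gives a purely coordinate-wise
#'   (diagonal) synergy rule. Default 0.05 keeps the planted signal
#'   dominantly recoverable from product features while remaining a genuine
#'   full bilinear form.
#' @param seed RNG seed; per-artifact seeds are derived from it by fixed
#'   offsets so the store, oracle and pair sample can be regenerated
#'   independently.
#' @return A validated list of class `SyntheticSpec`.
#' @examples
#' syntheticSpec(nProteins = 10, dim = 8, seed = 1)
#' @export
syntheticSpec <- function(nProteins, dim = 1024L, tailDf = 3, ruleRank = 4L,
                          labelNoise = 0, posFrac = 0.5, offDiag = 0.05,
                          seed = 1L) {
  spec <- list(
    nProteins = assertCount(nProteins, "nProteins", min = 1L),
    dim = assertCount(dim, "dim", min = 1L),
    tailDf = assertFraction(tailDf, "tailDf", lo = 2, hi = Inf),
    ruleRank = assertCount(ruleRank, "ruleRank", min = 1L),
    labelNoise = assertFraction(labelNoise, "labelNoise", lo = 0, hi = 0.5,
                                openLo = FALSE),
    posFrac = assertFraction(posFrac, "posFrac"),
    offDiag = assertFraction(offDiag, "offDiag", lo = 0, hi = 1, openLo = FALSE),
    seed = assertCount(seed, "seed", min = 0L)
  )
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic embedding store
#'
#' Draws `nProteins` embedding vectors of length `dim` with i.i.d.
#' coordinates from a Student-t with `tailDf` degrees of freedom, scaled to
#' unit variance. Identifiers are zero-padded (`"P000001"`, ...).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [syntheticSpec()].
#' @return An [EmbeddingStore-class].
#' @examples
#' generateProteinEmbeddings(syntheticSpec(4, dim = 3, seed = 7))
#' @export
generateProteinEmbeddings <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(deriveSeed(spec$seed, "store"))
  scale <- sqrt((spec$tailDf - 2) / spec$tailDf)  # unit-variance Student-t
  m <- matrix(stats::rt(spec$nProteins * spec$dim, df = spec$tailDf) * scale,
              nrow = spec$nProteins, ncol = spec$dim)
  rownames(m) <- sprintf("P%06d", seq_len(spec$nProteins))
  EmbeddingStore(m)
}

## Symmetric low-rank scoring matrix: rank-r sum of spiked eigenvectors
## v_j = sqrt(1-g^2) e_{k_j} + g w_j with positive weights, so coordinate-wise
## synergy (product features) carries the dominant, linearly recoverable
## signal while off-diagonal bilinear terms remain present for g > 0.
plantedMatrix <- function(dim, ruleRank, offDiag) {
  axes <- sample.int(dim, ruleRank, replace = FALSE)
  lambda <- 0.5 + stats::rexp(ruleRank)
  M <- matrix(0, dim, dim)
  for (j in seq_len(ruleRank)) {
    w <- stats::rnorm(dim)
    w <- w / sqrt(sum(w^2))
    v <- sqrt(1 - offDiag^2) * replace(numeric(dim), axes[j], 1) + offDiag * w
    M <- M + lambda[j] * tcrossprod(v)
  }
  M
}

#' Plant a symmetric bilinear interaction rule over a store
#'
#' Builds a rank-`ruleRank` symmetric matrix M and calibrates the threshold
#' tau as the empirical (1 - posFrac) quantile of scores
#' `x_a' ((M + M') / 2) x_b` over a seeded sample of at least
#' `nCalibration` random pairs, so that the planted positive rate is
#' approximately `posFrac`.
#'
#' @param store an [EmbeddingStore-class].
#' @param spec the [syntheticSpec()] used to generate the store.
#' @param nCalibration number of pairs sampled for threshold calibration.
#' @return An [InteractionOracle-class].
#' @export
plantInteractionRule <- function(store, spec, nCalibration = 20000L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  X <- embeddingMatrix(store)
  if (nrow(X) < 2L) stopf("store must contain at least 2 proteins")
  if (spec$ruleRank > spec$dim) {
    stopf("ruleRank (%d) exceeds embedding dim (%d)", spec$ruleRank, spec$dim)
  }
  set.seed(deriveSeed(spec$seed, "oracle"))
  M <- plantedMatrix(spec$dim, spec$ruleRank, spec$offDiag)
  M <- (M + t(M)) / 2
  ia <- sample.int(nrow(X), nCalibration, replace = TRUE)
  ib <- sample.int(nrow(X), nCalibration, replace = TRUE)
  scores <- rowSums((X[ia, , drop = FALSE] %*% M) * X[ib, , drop = FALSE])
  if (max(abs(scores)) < 1e-12 || stats::sd(scores) < 1e-12) {
    stopf("degenerate interaction rule: calibration scores have no spread")
  }
  tau <- stats::quantile(scores, probs = 1 - spec$posFrac, names = FALSE,
                         type = 7)
  new("InteractionOracle", M = M, tau = tau, posFrac = spec$posFrac,
      ruleRank = spec$ruleRank)
}

#' Score and label protein pairs under a planted rule
#'
#' @param oracle an [InteractionOracle-class].
#' @param store the [EmbeddingStore-class] the rule was planted over.
#' @param a,b character identifier vectors of equal length.
#' @return `oracleScores()`: numeric scores (symmetric in a, b);
#'   `oracleLabels()`: integer 0/1 labels from thresholding at tau.
#' @export
oracleScores <- function(oracle, store, a, b) {
  X <- embeddingMatrix(store)
  unname(rowSums((X[a, , drop = FALSE] %*% oracle@M) * X[b, , drop = FALSE]))
}

#' @rdname oracleScores
#' @export
oracleLabels <- function(oracle, store, a, b) {
  as.integer(oracleScores(oracle, store, a, b) > oracle@tau)
}

#' Sample a labeled pair dataset from a planted rule
#'
#' Draws `nPairs` distinct unordered protein pairs (no self-pairs, no
#' symmetric duplicates), labels them with the oracle, and flips each label
#' independently with probability `spec$labelNoise`. Pairs are returned in
#' canonical order (protein_a <= protein_b lexicographically).
#'
#' @param store an [EmbeddingStore-class].
#' @param oracle the matching [InteractionOracle-class].
#' @param nPairs number of pairs; must not exceed choose(nProteins, 2).
#' @param spec the [syntheticSpec()] (provides labelNoise and the seed).
#' @return A [PairTable-class].
#' @export
samplePairDataset <- function(store, oracle, nPairs, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  nPairs <- assertCount(nPairs, "nPairs", min = 1L)
  ids <- proteinIds(store)
  n <- length(ids)
  maxPairs <- n * (n - 1) / 2
  if (nPairs > maxPairs) {
    stopf("nPairs (%d) exceeds the %d distinct unordered pairs of %d proteins",
          nPairs, maxPairs, n)
  }
  set.seed(deriveSeed(spec$seed, "pairs"))
  if (nPairs > 0.5 * maxPairs || maxPairs <= 200000) {
    ## dense regime: enumerate all unordered index pairs and sample
    all <- utils::combn(n, 2L)
    keep <- if (nPairs == maxPairs) seq_len(maxPairs) else
      sample.int(maxPairs, nPairs, replace = FALSE)
    ia <- all[1L, keep]
    ib <- all[2L, keep]
  } else {
    ## sparse regime: rejection-sample unordered pairs until nPairs distinct
    ia <- integer(0); ib <- integer(0)
    key <- character(0)
    while (length(ia) < nPairs) {
      m <- ceiling((nPairs - length(ia)) * 1.3) + 16L
      ca <- sample.int(n, m, replace = TRUE)
      cb <- sample.int(n, m, replace = TRUE)
      lo <- pmin(ca, cb); hi <- pmax(ca, cb)
      ok <- lo != hi
      k <- paste(lo[ok], hi[ok])
      new <- !duplicated(k) & !(k %in% key)
      ia <- c(ia, lo[ok][new]); ib <- c(ib, hi[ok][new])
      key <- c(key, k[new])
    }
    ia <- ia[seq_len(nPairs)]; ib <- ib[seq_len(nPairs)]
  }
  a <- ids[ia]; b <- ids[ib]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  y <- oracleLabels(oracle, store, a, b)
  if (spec$labelNoise > 0) {
    flip <- stats::runif(nPairs) < spec$labelNoise
    y[flip] <- 1L - y[flip]
  }
  PairTable(data.frame(protein_a = a, protein_b = b, label = y,
                       stringsAsFactors = FALSE))
}

#' Generate a full synthetic benchmark in one call
#'
#' Convenience wrapper: store, planted rule, and a sampled pair table.
#'
#' @inheritParams samplePairDataset
#' @param spec a [syntheticSpec()].
#' @param nPairs number of pairs to sample.
#' @return list with elements `store`, `oracle`, `pairs`.
#' @export
simulateBenchmark <- function(spec, nPairs) {
  store <- generateProteinEmbeddings(spec)
  oracle <- plantInteractionRule(store, spec)
  pairs <- samplePairDataset(store, oracle, nPairs, spec)
  list(store = store, oracle = oracle, pairs = pairs)
}
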