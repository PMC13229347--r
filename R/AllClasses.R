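#' @import methods
NULL

#' Identifier-indexed store of per-protein embedding vectors
#'
#' Wraps an N x D numeric matrix whose rownames are unique protein
#' identifiers. Rows are the fixed-length embedding vectors consumed by the
#' model (1024 dimensions for typical protein language-model output; any
#' D >= 1 is accepted).
#'
#' @slot embeddings numeric matrix with unique, non-empty rownames.
#' @export
setClass("EmbeddingStore", representation(embeddings = "matrix"))

setValidity("EmbeddingStore", function(object) {
  m <- object@embeddings
  if (!is.numeric(m)) return("embeddings must be a numeric matrix")
  ids <- rownames(m)
  if (is.null(ids) || any(!nzchar(ids))) {
    return("embeddings must have non-empty rownames (protein identifiers)")
  }
  if (anyDuplicated(ids)) return("duplicated protein identifiers")
  if (any(!is.finite(m))) return("embeddings must be finite")
  TRUE
})

#' Construct an EmbeddingStore
#'
#' @param embeddings numeric matrix (proteins x dimensions) with protein
#'   identifiers as rownames.
#' @return An [EmbeddingStore-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("P1", "P2"), NULL))
#' EmbeddingStore(m)
#' @export
EmbeddingStore <- function(embeddings) {
  new("EmbeddingStore", embeddings = embeddings)
}

#' Labeled protein-pair table
#'
#' Records of (protein_a, protein_b, label) with binary labels: 1 for an
#' interacting pair, 0 for a non-interacting pair. Canonical form (as
#' produced by [canonicalizeAndDedup()]) orders each pair lexicographically
#' with protein_a <= protein_b and contains no duplicate unordered pairs.
#'
#' @slot pairs data.frame with character columns `protein_a`, `protein_b`
#'   and an integer `label` column containing only 0/1.
#' @export
setClass("PairTable", representation(pairs = "data.frame"))

setValidity("PairTable", function(object) {
  df <- object@pairs
  need <- c("protein_a", "protein_b", "label")
  if (!all(need %in% names(df))) {
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  }
  if (!all(df$label %in% c(0L, 1L))) return("labels must be 0 or 1")
  TRUE
})

#' Construct a PairTable
#'
#' @param pairs data.frame with columns `protein_a`, `protein_b`, `label`
#'   (labels in 0/1).
#' @return A [PairTable-class] object.
#' @export
PairTable <- function(pairs) {
  pairs$protein_a <- as.character(pairs$protein_a)
  pairs$protein_b <- as.character(pairs$protein_b)
  pairs$label <- as.integer(pairs$label)
  rownames(pairs) <- NULL
  new("PairTable", pairs = pairs)
}

#' Planted pairwise interaction rule
#'
#' A symmetric bilinear scoring rule over embedding space: a pair (a, b)
#' scores x_a' M x_b (M symmetric, low rank) and is labeled interacting when
#' the score exceeds the calibrated threshold `tau`. Used by the synthetic
#' benchmark as ground truth.
#'
#' @slot M symmetric dim x dim scoring matrix of rank `ruleRank`.
#' @slot tau numeric threshold, the empirical (1 - posFrac) quantile of
#'   scores over a seeded sample of pairs.
#' @slot posFrac target positive fraction used for calibration.
#' @slot ruleRank rank of M.
#' @export
setClass("InteractionOracle",
         representation(M = "matrix", tau = "numeric",
                        posFrac = "numeric", ruleRank = "integer"))

setValidity("InteractionOracle", function(object) {
  if (nrow(object@M) != ncol(object@M)) return("M must be square")
  if (max(abs(object@M - t(object@M))) > 1e-8) return("M must be symmetric")
  if (length(object@tau) != 1L || !is.finite(object@tau)) {
    return("tau must be a single finite number")
  }
  TRUE
})

#' Median/IQR robust scaler parameters
#'
#' Per-dimension centering and scaling statistics fitted on training
#' embeddings: `center` is the column median, `scale` the interquartile
#' range Q3 - Q1 under the linear-interpolation (type 7) quantile
#' convention. Dimensions whose IQR falls below `iqrFloor` are centered but
#' left unscaled (scale set to 1).
#'
#' @slot center numeric vector of per-dimension medians.
#' @slot scale numeric vector of per-dimension (floored) IQRs, all > 0.
#' @slot iqrFloor threshold below which an IQR is considered degenerate.
#' @slot quantileType quantile convention used (7).
#' @slot fittedOn md5 digest of the serialized training matrix, for
#'   provenance.
#' @export
setClass("RobustScaler",
         representation(center = "numeric", scale = "numeric",
                        iqrFloor = "numeric", quantileType = "integer",
                        fittedOn = "character"))

setValidity("RobustScaler", function(object) {
  if (length(object@center) != length(object@scale)) {
    return("center and scale must have equal length")
  }
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})

#' Train/validation/test partition of a pair table
#'
#' @slot train,val,test [PairTable-class] partitions.
#' @slot provenance list recording the seed, fractions and sizes used.
#' @export
setClass("DatasetSplits",
         representation(train = "PairTable", val = "PairTable",
                        test = "PairTable", provenance = "list"))

#' Quad-stream attention model
#'
#' Holds the full parameter set (a named list of matrices/vectors) and the
#' architecture configuration of the quad-stream attention network: four
#' per-stream attention blocks, four cross-attention exchanges, the fusion
#' network and the four task heads.
#'
#' @slot params named list of numeric parameter arrays.
#' @slot config architecture configuration as returned by
#'   [attentionConfig()].
#' @export
setClass("QuadNetModel", representation(params = "list", config = "list"))
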