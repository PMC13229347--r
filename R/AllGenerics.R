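#' Protein identifiers of a store or pair table
#'
#' @param x an [EmbeddingStore-class] (row identifiers) or
#'   [PairTable-class] (unique identifiers across both columns).
#' @return character vector of identifiers.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "EmbeddingStore", function(x) rownames(x@embeddings))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "PairTable", function(x) {
  unique(c(x@pairs$protein_a, x@pairs$protein_b))
})

#' Embedding matrix of a store
#'
#' @param x an [EmbeddingStore-class].
#' @return numeric matrix (proteins x dimensions), identifiers as rownames.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname embeddingMatrix
#' @export
setMethod("embeddingMatrix", "EmbeddingStore", function(x) x@embeddings)

#' Pair records as a data.frame
#'
#' @param x a [PairTable-class].
#' @return data.frame with columns `protein_a`, `protein_b`, `label`.
#' @export
setGeneric("pairRecords", function(x) standardGeneric("pairRecords"))

#' @rdname pairRecords
#' @export
setMethod("pairRecords", "PairTable", function(x) x@pairs)

#' Class counts of a pair table
#'
#' @param x a [PairTable-class].
#' @return named integer vector with elements `n_pos` and `n_neg`.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname classCounts
#' @export
setMethod("classCounts", "PairTable", function(x) {
  c(n_pos = sum(x@pairs$label == 1L), n_neg = sum(x@pairs$label == 0L))
})

#' Number of pair records
#'
#' @param x a [PairTable-class].
#' @export
setMethod("length", "PairTable", function(x) nrow(x@pairs))

#' Subset an embedding store by identifier or index
#'
#' @param x an [EmbeddingStore-class].
#' @param i character identifiers or numeric indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "EmbeddingStore", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    missing <- setdiff(i, rownames(x@embeddings))
    if (length(missing)) {
      stopf("unknown protein identifier(s): %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  EmbeddingStore(x@embeddings[i, , drop = FALSE])
})

#' Train/validation/test accessors
#'
#' @param x a [DatasetSplits-class].
#' @return the corresponding [PairTable-class].
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))
#' @rdname trainSet
#' @export
setGeneric("valSet", function(x) standardGeneric("valSet"))
#' @rdname trainSet
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))
#' @rdname trainSet
#' @export
setMethod("trainSet", "DatasetSplits", function(x) x@train)
#' @rdname trainSet
#' @export
setMethod("valSet", "DatasetSplits", function(x) x@val)
#' @rdname trainSet
#' @export
setMethod("testSet", "DatasetSplits", function(x) x@test)

#' Model parameters and configuration
#'
#' @param x a [QuadNetModel-class].
#' @return `modelParams()`: the named list of parameter arrays;
#'   `modelConfig()`: the architecture configuration list.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname modelParams
#' @export
setMethod("modelParams", "QuadNetModel", function(x) x@params)
#' @rdname modelParams
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname modelParams
#' @export
setMethod("modelConfig", "QuadNetModel", function(x) x@config)

setMethod("show", "EmbeddingStore", function(object) {
  d <- dim(object@embeddings)
  cat(sprintf("EmbeddingStore: %d proteins x %d dimensions\n", d[1L], d[2L]))
  ids <- rownames(object@embeddings)
  cat("  ids:", paste(utils::head(ids, 3L), collapse = ", "),
      if (length(ids) > 3L) "..." else "", "\n")
})

setMethod("show", "PairTable", function(object) {
  cc <- classCounts(object)
  cat(sprintf("PairTable: %d pairs (%d positive, %d negative)\n",
              nrow(object@pairs), cc[["n_pos"]], cc[["n_neg"]]))
})

setMethod("show", "InteractionOracle", function(object) {
  cat(sprintf(
    "InteractionOracle: %dx%d symmetric bilinear rule, rank %d, tau = %.4g (pos_frac %.2f)\n",
    nrow(object@M), ncol(object@M), object@ruleRank, object@tau, object@posFrac))
})

setMethod("show", "RobustScaler", function(object) {
  cat(sprintf(
    "RobustScaler: %d dimensions (median/IQR, quantile type %d, %d floored)\n",
    length(object@center), object@quantileType,
    sum(object@scale == 1 & object@iqrFloor > 0)))
})

setMethod("show", "DatasetSplits", function(object) {
  cat(sprintf("DatasetSplits: train %d / val %d / test %d\n",
              length(object@train), length(object@val), length(object@test)))
})

setMethod("show", "QuadNetModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "QuadNetModel: input %d -> hidden %d (%d tokens, %d heads), %d type classes, %d parameters\n",
    cfg$inputDim, cfg$hiddenDim, cfg$nTokens, cfg$numHeads, cfg$numTypes, np))
})
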