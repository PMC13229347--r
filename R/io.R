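## On-disk formats: TSV embedding store with a plain-text identifier
## sidecar, TSV pair tables, JSON scaler manifests, and model checkpoints.

#' Read / write an embedding store
#'
#' The store is a tab-separated matrix with an `id` column followed by the
#' embedding dimensions (`d1` ... `dD`), plus a plain-text sidecar index
#' (`<prefix>.index.txt`, one identifier per line) for fast inspection
#' without parsing the matrix.
#'
#' @param store an [EmbeddingStore-class].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.index.txt`.
#' @return `writeEmbeddingStore()`: the prefix, invisibly;
#'   `readEmbeddingStore()`: an [EmbeddingStore-class].
#' @export
writeEmbeddingStore <- function(store, prefix) {
  m <- embeddingMatrix(store)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("d", seq_len(ncol(m))))
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(rownames(m), paste0(prefix, ".index.txt"))
  invisible(prefix)
}

#' @rdname writeEmbeddingStore
#' @export
readEmbeddingStore <- function(prefix) {
  path <- if (file.exists(prefix)) prefix else paste0(prefix, ".tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(df[[1L]], NULL)
  EmbeddingStore(m)
}

#' Read / write a pair table
#'
#' Tab-separated with header `protein_a  protein_b  label`.
#'
#' @param pairs a [PairTable-class].
#' @param path file path.
#' @return `writePairTable()`: the path, invisibly; `readPairTable()`: a
#'   [PairTable-class].
#' @export
writePairTable <- function(pairs, path) {
  utils::write.table(pairRecords(pairs), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path) {
  PairTable(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Persist / restore a robust scaler as JSON
#'
#' The manifest records the center, scale, floor and quantile convention
#' so a scaling is exactly reproducible.
#'
#' @param scaler a [RobustScaler-class].
#' @param path JSON file path.
#' @return `saveScaler()`: the path, invisibly; `loadScaler()`: a
#'   [RobustScaler-class].
#' @export
saveScaler <- function(scaler, path) {
  jsonlite::write_json(
    list(center = scaler@center, scale = scaler@scale,
         iqr_floor = scaler@iqrFloor, quantile_type = scaler@quantileType,
         fitted_on = scaler@fittedOn),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveScaler
#' @export
loadScaler <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RobustScaler", center = as.numeric(j$center),
      scale = as.numeric(j$scale), iqrFloor = as.numeric(j$iqr_floor),
      quantileType = as.integer(j$quantile_type),
      fittedOn = if (is.null(j$fitted_on)) NA_character_ else j$fitted_on)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a serialized parameter set; a JSON manifest with the
#' architecture configuration is written alongside
#' (`<path>.manifest.json`) so the file is self-describing.
#'
#' @param model a [QuadNetModel-class].
#' @param path checkpoint file path.
#' @return `saveCheckpoint()`: the path, invisibly; `loadCheckpoint()`: a
#'   [QuadNetModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = modelParams(model), config = modelConfig(model)),
          path)
  jsonlite::write_json(modelConfig(model), paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("QuadNetModel", params = x$params, config = x$config)
}

#' Write a split directory with manifest
#'
#' Writes `train.tsv`, `val.tsv`, `test.tsv` and a `manifest.json`
#' recording sizes, class counts, seed and the leakage audit.
#'
#' @param splits a [DatasetSplits-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSplits <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePairTable(trainSet(splits), file.path(dir, "train.tsv"))
  writePairTable(valSet(splits), file.path(dir, "val.tsv"))
  writePairTable(testSet(splits), file.path(dir, "test.tsv"))
  counts <- function(pt) as.list(classCounts(pt))
  jsonlite::write_json(
    c(splits@provenance,
      list(leakage = auditLeakage(splits),
           train = c(list(n = length(trainSet(splits))), counts(trainSet(splits))),
           val = c(list(n = length(valSet(splits))), counts(valSet(splits))),
           test = c(list(n = length(testSet(splits))), counts(testSet(splits))))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
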